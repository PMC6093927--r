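#' d' decodability on a feature matrix
#'
#' Applies the identical projection-based [dprime()] machinery to an
#' arbitrary stimulus x unit feature matrix (e.g. the output of one layer
#' of a hierarchical model), under the same pooled / per-condition schemes
#' as the electrode-space analysis. Pair averaging follows
#' [average_pairs()]: the category value averages all 6 category pairs,
#' each variation dimension averages its 3 level pairs.
#'
#' @param features Numeric matrix, stimuli x units.
#' @param design Design table aligned to the rows of `features` (one row
#'   per stimulus, repeated rows allowed for repeated presentations).
#' @param contrast A [contrast_category()] or [contrast_variation()].
#' @param scheme `"pooled"` or `"per_condition"`.
#' @return Scalar d'.
#' @export
layer_dprime <- function(features, design, contrast,
                         scheme = c("pooled", "per_condition")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(features), nrow(features) == nrow(design))
  masks <- contrast_masks(contrast, design)
  strata <- decode_strata(contrast, design, scheme)
  vals <- c()
  for (s in strata) {
    ia <- which(masks$a & s); ib <- which(masks$b & s)
    if (length(ia) < 2L || length(ib) < 2L) {
      warning("stratum skipped: fewer than 2 stimuli per cluster")
      next
    }
    vals <- c(vals, dprime(features[ia, , drop = FALSE],
                           features[ib, , drop = FALSE]))
  }
  if (length(vals) == 0L) stop("all strata skipped; no cluster had >= 2 stimuli")
  mean(vals)
}

#' Per-layer decodability profiles
#'
#' For each layer: the pair-averaged category d' and the pair-averaged d'
#' of each variation dimension (plus their mean across dimensions).
#'
#' @param layers List of stimulus x unit feature matrices, one per layer.
#' @param design Design table aligned to the rows.
#' @param scheme Decoding scheme.
#' @return Data frame with one row per layer: `layer`, `category`, one
#'   column per variation dimension, and `variation_mean`.
#' @export
layer_profiles <- function(layers, design, scheme = "pooled") {
  prof <- lapply(seq_along(layers), function(l) {
    f <- layers[[l]]
    cat_pairs <- utils::combn(CATEGORIES, 2, simplify = FALSE)
    cat_d <- mean(vapply(cat_pairs, function(p) {
      layer_dprime(f, design, contrast_category(p[1], p[2]), scheme)
    }, 0))
    var_d <- vapply(VARIATION_TYPES, function(vt) {
      lev_pairs <- utils::combn(1:3, 2, simplify = FALSE)
      mean(vapply(lev_pairs, function(p) {
        layer_dprime(f, design, contrast_variation(vt, p[1], p[2]), scheme)
      }, 0))
    }, 0)
    c(category = cat_d, var_d, variation_mean = mean(var_d))
  })
  out <- as.data.frame(do.call(rbind, prof))
  cbind(layer = seq_along(layers), out)
}

#' Sliding correlation over consecutive layers
#'
#' Pearson correlation between two per-layer profiles over each run of
#' `window` consecutive layers (3 by default), tracking whether category
#' and variation decodability rise and fall together along the hierarchy.
#'
#' @param a,b Numeric per-layer profiles of equal length.
#' @param window Layers per window.
#' @return Data frame `first_layer`, `last_layer`, `r` (NA where a window
#'   has zero variance).
#' @export
layer_sliding_correlation <- function(a, b, window = 3L) {
  stopifnot(length(a) == length(b), length(a) >= window)
  n <- length(a) - window + 1L
  r <- vapply(seq_len(n), function(i) {
    w <- i:(i + window - 1L)
    if (stats::sd(a[w]) == 0 || stats::sd(b[w]) == 0) NA_real_
    else stats::cor(a[w], b[w])
  }, 0)
  data.frame(first_layer = seq_len(n), last_layer = seq_len(n) + window - 1L, r = r)
}

#' Correlation between a profile and layer dimensionality
#'
#' @param profile Per-layer decodability values.
#' @param layer_dims Per-layer representational dimensionalities (number
#'   of units).
#' @return Pearson r.
#' @export
dimension_correlation <- function(profile, layer_dims) {
  if (length(profile) != length(layer_dims)) {
    stop("profile and layer_dims have different lengths")
  }
  stats::cor(profile, layer_dims)
}

#' Synthetic layer cascade with scheduled separability
#'
#' Generates per-layer Gaussian feature matrices for the 192-stimulus
#' design in which category and variation separability follow
#' user-supplied per-layer schedules: each category (and each variation
#' level of each dimension) gets a random unit-norm centroid direction,
#' scaled by the schedule value for that layer, plus unit Gaussian noise.
#' Opposing schedules reproduce the qualitative two-regime pattern where
#' category and variation decodability first rise together and then
#' decouple across layers.
#'
#' @param design Design table.
#' @param n_units Units per layer (recycled).
#' @param cat_sep,var_sep Per-layer separability multipliers; equal
#'   lengths define the number of layers.
#' @param seed Integer seed.
#' @return List of stimulus x unit matrices.
#' @export
layer_cascade <- function(design = generate_design(), n_units = 50L,
                          cat_sep, var_sep, seed = 1L) {
  stopifnot(length(cat_sep) == length(var_sep))
  n_layers <- length(cat_sep)
  n_units <- rep_len(n_units, n_layers)
  set.seed(as.integer(seed))
  lapply(seq_len(n_layers), function(l) {
    nu <- n_units[l]
    unit_dir <- function() { v <- stats::rnorm(nu); v / sqrt(sum(v * v)) }
    cat_cent <- vapply(CATEGORIES, function(i) unit_dir(), numeric(nu))
    var_cent <- array(vapply(seq_len(length(VARIATION_TYPES) * N_LEVELS),
                             function(i) unit_dir(), numeric(nu)),
                      dim = c(nu, N_LEVELS, length(VARIATION_TYPES)),
                      dimnames = list(NULL, NULL, VARIATION_TYPES))
    f <- matrix(stats::rnorm(nrow(design) * nu), nrow = nrow(design))
    for (i in seq_len(nrow(design))) {
      f[i, ] <- f[i, ] + cat_sep[l] * cat_cent[, design$category[i]] +
        var_sep[l] * var_cent[, design$variation_level[i], design$variation_type[i]]
    }
    f
  })
}
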