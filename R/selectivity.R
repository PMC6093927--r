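aspect_table <- function() {
  data.frame(
    dimension = c(rep("category", 4), rep(VARIATION_TYPES, each = N_LEVELS)),
    condition = c(CATEGORIES,
                  as.character(rep(seq_len(N_LEVELS), times = length(VARIATION_TYPES)))),
    stringsAsFactors = FALSE)
}

#' Per-electrode decodability vectors for every information aspect
#'
#' An "aspect" is one decodable distinction taken one-vs-rest: a category
#' against the other three (average of its three pairwise curves), or one
#' level of a variation dimension against the other two levels (average of
#' its two pairwise curves). Each aspect yields a vector of univariate d'
#' values, one per analysis electrode, at the requested time point;
#' clusters are pooled over the remaining design dimensions so every vector
#' uses all eligible trials.
#'
#' @param epochs One subject's `eeg_epochs`.
#' @param time_ms Time point (must lie inside the epoch); the nearest bin
#'   is used.
#' @param baseline Subtract each electrode's pre-stimulus mean d' first?
#'   Pearson correlation between aspect vectors is not invariant to this
#'   (the shift differs per electrode), so both variants are meaningful;
#'   the default is the raw vectors.
#' @return Matrix aspects x electrodes (16 x 31 at the full design), with
#'   aspect ids as row names.
#' @export
aspect_vectors <- function(epochs, time_ms, baseline = FALSE) {
  stopifnot_epochs(epochs)
  time <- epochs$time
  if (time_ms < min(time) || time_ms > max(time)) {
    stop("time ", time_ms, " ms lies outside the epoch")
  }
  tb <- which.min(abs(time - time_ms))
  aspect_grids(epochs, baseline)[, , tb]
}

# aspects x channels x bins array of one-vs-rest averaged univariate d'
aspect_grids <- function(epochs, baseline = FALSE) {
  asp <- aspect_table()
  nch <- length(epochs$channels)
  nb <- length(epochs$time)
  pair_grid <- function(contrast) {
    g <- electrode_dprime_grid(epochs, contrast, "pooled")
    if (baseline) g <- g - rowMeans(g[, baseline_bins(epochs$time), drop = FALSE])
    g
  }
  # unique pairwise grids, each reused by the two aspects it involves
  cache <- new.env(parent = emptyenv())
  get_pair <- function(key, contrast) {
    if (!exists(key, cache)) assign(key, pair_grid(contrast), cache)
    get(key, cache)
  }
  out <- array(NA_real_, dim = c(nrow(asp), nch, nb),
               dimnames = list(paste(asp$dimension, asp$condition, sep = ":"),
                               epochs$channels, NULL))
  for (i in seq_len(nrow(asp))) {
    acc <- matrix(0, nch, nb); k <- 0L
    if (asp$dimension[i] == "category") {
      for (o in setdiff(CATEGORIES, asp$condition[i])) {
        pr <- sort(c(asp$condition[i], o))
        acc <- acc + get_pair(paste0("cat:", pr[1], ":", pr[2]),
                              contrast_category(pr[1], pr[2]))
        k <- k + 1L
      }
    } else {
      lev <- as.integer(asp$condition[i])
      for (o in setdiff(seq_len(N_LEVELS), lev)) {
        pr <- sort(c(lev, o))
        acc <- acc + get_pair(paste0(asp$dimension[i], ":", pr[1], ":", pr[2]),
                              contrast_variation(asp$dimension[i], pr[1], pr[2]))
        k <- k + 1L
      }
    }
    out[i, , ] <- acc / k
  }
  out
}

#' Information-selectivity matrix
#'
#' Pairwise Pearson correlations between the per-electrode decodability
#' vectors of all aspects at one time point. High off-diagonal correlation
#' means two aspects are carried by overlapping electrode sets.
#'
#' @param vectors Aspects x electrodes matrix from [aspect_vectors()] (or
#'   any >= 2 equal-length rows).
#' @return Symmetric correlation matrix with unit diagonal; rows with zero
#'   variance produce NA correlations with a warning.
#' @export
selectivity_matrix <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2L)
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance aspect vector(s); their ",
            "correlations are NA")
  }
  suppressWarnings(m <- stats::cor(t(vectors)))
  diag(m) <- 1
  m
}

#' Information-selectivity index of one matrix
#'
#' Mean of the off-diagonal correlations between aspects of the same
#' dimension block (category with category, each variation dimension's
#' levels with each other) minus the mean of all correlations crossing
#' blocks. Positive values mean within-dimension electrode patterns
#' resemble each other more than across dimensions, i.e. distinct
#' electrode sets carry distinct kinds of information. The index lies in
#' [-2, 2]; missing entries are dropped from both means.
#'
#' @param m Selectivity matrix from [selectivity_matrix()].
#' @param blocks Block label per row; defaults to the 16-aspect layout
#'   (dimension name before the `:` in the row names).
#' @return Scalar index.
#' @examples
#' m <- matrix(0.2, 7, 7); m[1:4, 1:4] <- 0.8; m[5:7, 5:7] <- 0.8; diag(m) <- 1
#' selectivity_index(m, c(rep("a", 4), rep("b", 3)))  # 0.6
#' @export
selectivity_index <- function(m, blocks = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(blocks)) {
    if (is.null(rownames(m))) stop("blocks not given and matrix has no row names")
    blocks <- sub(":.*$", "", rownames(m))
  }
  stopifnot(length(blocks) == nrow(m))
  same <- outer(blocks, blocks, "==")
  off <- !diag(nrow(m))
  within <- m[same & off]
  between <- m[!same]
  n_miss <- sum(is.na(within)) + sum(is.na(between))
  if (n_miss > 0) message(n_miss, " missing entries excluded from the index")
  mean(within, na.rm = TRUE) - mean(between, na.rm = TRUE)
}

#' Time-resolved selectivity index for a group
#'
#' @param group List of `eeg_epochs` (one per subject).
#' @param times_ms Time points to evaluate.
#' @param baseline Passed to [aspect_vectors()].
#' @return Data frame `time_ms`, `mean`, `sem` plus a subjects x times
#'   matrix in attribute `"values"`.
#' @export
selectivity_trace <- function(group, times_ms, baseline = FALSE) {
  vals <- vapply(group, function(ep) {
    grids <- aspect_grids(ep, baseline)
    vapply(times_ms, function(tt) {
      tb <- which.min(abs(ep$time - tt))
      selectivity_index(selectivity_matrix(grids[, , tb]))
    }, 0)
  }, numeric(length(times_ms)))
  vals <- matrix(vals, nrow = length(times_ms))  # times x subjects
  out <- data.frame(time_ms = times_ms,
                    mean = rowMeans(vals),
                    sem = apply(vals, 1, stats::sd) / sqrt(ncol(vals)))
  attr(out, "values") <- t(vals)
  out
}
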