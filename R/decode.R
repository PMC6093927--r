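#' Condition contrasts
#'
#' A contrast names the two condition clusters a decodability curve
#' separates: two categories (trials pooled over, or stratified by,
#' variation conditions) or two levels of one variation dimension.
#'
#' @param a,b The two categories, e.g. `"car"`, `"face"`.
#' @return A `contrast` list.
#' @export
contrast_category <- function(a, b) {
  stopifnot(a %in% CATEGORIES, b %in% CATEGORIES, a != b)
  structure(list(dimension = "category", a = a, b = b,
                 label = paste0("category:", a, "-", b)), class = "contrast")
}

#' @rdname contrast_category
#' @param type Variation dimension (`"size"`, `"position"`, `"pose"`,
#'   `"lighting"`).
#' @param level_a,level_b The two levels (1-3) being contrasted.
#' @export
contrast_variation <- function(type, level_a, level_b) {
  stopifnot(type %in% VARIATION_TYPES, level_a %in% 1:3, level_b %in% 1:3,
            level_a != level_b)
  structure(list(dimension = "variation", type = type, a = level_a, b = level_b,
                 label = paste0(type, ":", level_a, "-", level_b)),
            class = "contrast")
}

contrast_masks <- function(contrast, trials) {
  if (contrast$dimension == "category") {
    list(a = trials$category == contrast$a, b = trials$category == contrast$b)
  } else {
    sel <- trials$variation_type == contrast$type
    list(a = sel & trials$variation_level == contrast$a,
         b = sel & trials$variation_level == contrast$b)
  }
}

new_curve <- function(values, time, contrast, scheme, electrodes,
                      baseline_corrected, baseline_window = c(-200, 0)) {
  structure(list(values = values, time = time, contrast = contrast,
                 scheme = scheme, electrodes = electrodes,
                 baseline_corrected = baseline_corrected,
                 baseline_window = baseline_window),
            class = "decod_curve")
}

#' @export
print.decod_curve <- function(x, ...) {
  cat("Decodability curve [", x$contrast, "], scheme ", x$scheme, ", ",
      length(x$values), " bins, baseline ",
      if (x$baseline_corrected) "corrected" else "raw", "\n", sep = "")
  invisible(x)
}

# trials x dims matrix for electrode rows e, bin t, trial indices idx
slice_trials <- function(V, e, t, idx) {
  m <- V[e, t, idx, drop = FALSE]
  matrix(m, nrow = length(e), ncol = length(idx))
}

baseline_bins <- function(time, window = c(-200, 0)) {
  which(time >= window[1] & time < window[2])
}

apply_baseline <- function(values, time, window = c(-200, 0)) {
  bl <- baseline_bins(time, window)
  if (length(bl) == 0L) stop("no bins inside the baseline window")
  values - mean(values[bl])
}

#' Time-resolved decodability between two conditions
#'
#' At every 5 ms bin, the trials of the two contrast conditions form two
#' clusters in the space of the selected electrodes and their separation is
#' summarized with [dprime()].
#'
#' Two schemes are supported. `pooled` clusters use every matching trial
#' regardless of the other design dimensions (category clusters pool all 12
#' variation conditions and vice versa), so category and variation
#' information may mix. `per_condition` isolates one dimension from the
#' other: category d' is computed separately within each of the 12
#' variation conditions and the curves averaged; variation-level d' is
#' computed within each of the 16 category exemplars (objects) and
#' averaged. A stratum whose clusters have fewer than 2 trials each is
#' skipped with a warning; if every stratum is skipped this is an error.
#'
#' With `baseline = TRUE` the mean d' over the last 200 ms before stimulus
#' onset is subtracted from the whole curve (per subject, per curve), so
#' pre-stimulus values scatter around zero.
#'
#' @param epochs An `eeg_epochs` object for one subject.
#' @param contrast A [contrast_category()] or [contrast_variation()].
#' @param scheme `"pooled"` or `"per_condition"`.
#' @param electrodes Electrode set: `"all"`, a preset name, or channel names.
#' @param baseline Subtract the pre-stimulus mean d'?
#' @param baseline_window ms pair defining the pre-stimulus reference.
#' @return A `decod_curve` with one d' value per time bin.
#' @export
decode_timecourse <- function(epochs, contrast,
                              scheme = c("pooled", "per_condition"),
                              electrodes = "all", baseline = TRUE,
                              baseline_window = c(-200, 0)) {
  stopifnot_epochs(epochs)
  scheme <- match.arg(scheme)
  chs <- electrode_preset(electrodes, epochs$channels)
  e <- match(chs, epochs$channels)
  trials <- epochs$trials
  masks <- contrast_masks(contrast, trials)
  if (!any(masks$a) || !any(masks$b)) {
    stop("contrast condition absent from the trial table: ", contrast$label)
  }
  V <- epochs$voltages
  nb <- dim(V)[2]

  strata <- decode_strata(contrast, trials, scheme)
  vals <- matrix(NA_real_, nrow = length(strata), ncol = nb)
  kept <- logical(length(strata))
  for (s in seq_along(strata)) {
    ia <- which(masks$a & strata[[s]])
    ib <- which(masks$b & strata[[s]])
    if (length(ia) < 2L || length(ib) < 2L) {
      warning("stratum ", s, " skipped: fewer than 2 trials per cluster")
      next
    }
    kept[s] <- TRUE
    for (t in seq_len(nb)) {
      vals[s, t] <- dprime(t(slice_trials(V, e, t, ia)),
                           t(slice_trials(V, e, t, ib)))
    }
  }
  if (!any(kept)) stop("all strata skipped; no cluster had >= 2 trials")
  curve <- colMeans(vals[kept, , drop = FALSE])
  if (baseline) curve <- apply_baseline(curve, epochs$time, baseline_window)
  new_curve(curve, epochs$time, contrast$label, scheme, chs, baseline,
            baseline_window)
}

decode_strata <- function(contrast, trials, scheme) {
  if (scheme == "pooled") return(list(rep(TRUE, nrow(trials))))
  if (contrast$dimension == "category") {
    grid <- expand.grid(level = 1:3, type = VARIATION_TYPES,
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) {
      trials$variation_type == grid$type[i] & trials$variation_level == grid$level[i]
    })
  } else {
    grid <- expand.grid(ex = seq_len(N_EXEMPLARS), cat = CATEGORIES,
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) {
      trials$category == grid$cat[i] & trials$exemplar == grid$ex[i]
    })
  }
}

#' All pairwise curves for one design dimension
#'
#' Convenience wrapper producing the 6 category-pair curves, or the 3
#' level-pair curves of one variation dimension.
#'
#' @inheritParams decode_timecourse
#' @param dimension `"category"` or a variation type.
#' @return Named list of `decod_curve`s.
#' @export
decode_all_pairs <- function(epochs, dimension = "category",
                             scheme = "pooled", electrodes = "all",
                             baseline = TRUE) {
  if (dimension == "category") {
    pairs <- utils::combn(CATEGORIES, 2, simplify = FALSE)
    contrasts <- lapply(pairs, function(p) contrast_category(p[1], p[2]))
  } else {
    pairs <- utils::combn(1:3, 2, simplify = FALSE)
    contrasts <- lapply(pairs, function(p) contrast_variation(dimension, p[1], p[2]))
  }
  out <- lapply(contrasts, decode_timecourse, epochs = epochs, scheme = scheme,
                electrodes = electrodes, baseline = baseline)
  names(out) <- vapply(contrasts, `[[`, "", "label")
  out
}

#' Average a set of decodability curves pointwise
#'
#' The grand-average curve for a dimension is the pointwise mean of all its
#' pair curves; the "one condition" variant averages the pair curves
#' involving that condition (three, for one category).
#'
#' @param curves List of `decod_curve`s on a common time axis.
#' @param label Label for the averaged curve.
#' @return A `decod_curve`.
#' @export
average_pairs <- function(curves, label = "pair-average") {
  stopifnot(length(curves) >= 1L)
  time <- curves[[1]]$time
  for (cv in curves) {
    if (length(cv$time) != length(time) || any(cv$time != time)) {
      stop("curves are on mismatched time axes")
    }
  }
  vals <- rowMeans(vapply(curves, `[[`, numeric(length(time)), "values"))
  new_curve(vals, time, label, curves[[1]]$scheme, curves[[1]]$electrodes,
            curves[[1]]$baseline_corrected, curves[[1]]$baseline_window)
}

#' Electrode-wise decodability map
#'
#' d' computed in the 1-D space of each electrode alone, averaged over the
#' bins within `center_ms +/- half_width_ms` (25 ms by default, i.e. an
#' 11-bin window at 5 ms). Baseline handling matches
#' [decode_timecourse()]: with `baseline = TRUE` each electrode's
#' pre-stimulus mean d' is subtracted before windowing.
#'
#' @inheritParams decode_timecourse
#' @param center_ms Map time point (ms).
#' @param half_width_ms Averaging half-window (ms).
#' @return Named numeric vector, one d' per analysis electrode.
#' @export
scalp_map <- function(epochs, contrast, scheme = c("pooled", "per_condition"),
                      center_ms, half_width_ms = 25, baseline = TRUE,
                      baseline_window = c(-200, 0)) {
  stopifnot_epochs(epochs)
  scheme <- match.arg(scheme)
  time <- epochs$time
  win <- which(time >= center_ms - half_width_ms & time <= center_ms + half_width_ms)
  if (center_ms - half_width_ms < min(time) || center_ms + half_width_ms > max(time)) {
    stop("averaging window [", center_ms - half_width_ms, ", ",
         center_ms + half_width_ms, "] ms exceeds the epoch")
  }
  grid <- electrode_dprime_grid(epochs, contrast, scheme)
  if (baseline) {
    bl <- baseline_bins(time, baseline_window)
    grid <- grid - rowMeans(grid[, bl, drop = FALSE])
  }
  out <- rowMeans(grid[, win, drop = FALSE])
  names(out) <- epochs$channels
  out
}

# channels x bins matrix of univariate d' values for a contrast
electrode_dprime_grid <- function(epochs, contrast, scheme = "pooled") {
  V <- epochs$voltages
  d <- dim(V)
  W <- matrix(V, nrow = d[1] * d[2])
  trials <- epochs$trials
  masks <- contrast_masks(contrast, trials)
  strata <- decode_strata(contrast, trials, scheme)
  acc <- matrix(0, nrow = d[1], ncol = d[2]); nk <- 0L
  for (s in strata) {
    ia <- which(masks$a & s); ib <- which(masks$b & s)
    if (length(ia) < 2L || length(ib) < 2L) next
    acc <- acc + matrix(dprime_univariate_grid(W, ia, ib), nrow = d[1])
    nk <- nk + 1L
  }
  if (nk == 0L) stop("all strata skipped; no cluster had >= 2 trials")
  acc / nk
}

#' Label-ignorant subsampled decodability curve
#'
#' Draws two disjoint random clusters of `n_per_cluster` trials (ignoring
#' all labels), computes the time-resolved d' between them, and averages
#' over `n_reps` draws. This is the chance-level reference for curves built
#' from labelled clusters of the same size.
#'
#' @inheritParams decode_timecourse
#' @param n_per_cluster Trials per random cluster; `2 * n_per_cluster` must
#'   not exceed the number of trials.
#' @param n_reps Number of random draws averaged.
#' @param seed Integer seed for the draws.
#' @return A `decod_curve`.
#' @export
random_subsample_curve <- function(epochs, n_per_cluster, n_reps = 1000,
                                   seed = 1L, electrodes = "all",
                                   baseline = TRUE, baseline_window = c(-200, 0)) {
  stopifnot_epochs(epochs)
  n_tr <- dim(epochs$voltages)[3]
  if (2L * n_per_cluster > n_tr) {
    stop("2 * n_per_cluster (", 2L * n_per_cluster, ") exceeds ", n_tr, " trials")
  }
  chs <- electrode_preset(electrodes, epochs$channels)
  e <- match(chs, epochs$channels)
  V <- epochs$voltages
  nb <- dim(V)[2]
  set.seed(as.integer(seed))
  acc <- numeric(nb)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(n_tr, 2L * n_per_cluster)
    ia <- pick[seq_len(n_per_cluster)]
    ib <- pick[n_per_cluster + seq_len(n_per_cluster)]
    for (t in seq_len(nb)) {
      acc[t] <- acc[t] + dprime(t(slice_trials(V, e, t, ia)),
                                t(slice_trials(V, e, t, ib)))
    }
  }
  curve <- acc / n_reps
  if (baseline) curve <- apply_baseline(curve, epochs$time, baseline_window)
  new_curve(curve, epochs$time, "random-subsample", "pooled", chs, baseline,
            baseline_window)
}

#' Stack per-subject curves into a group matrix
#'
#' @param curves List of `decod_curve`s (one per subject) on a common axis.
#' @return List with `values` (subjects x bins matrix), `time`, `mean`,
#'   `sem`.
#' @export
group_curves <- function(curves) {
  time <- curves[[1]]$time
  M <- t(vapply(curves, `[[`, numeric(length(time)), "values"))
  list(values = M, time = time, mean = colMeans(M),
       sem = apply(M, 2, stats::sd) / sqrt(nrow(M)))
}
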