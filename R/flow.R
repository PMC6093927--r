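#' Representational similarity matrix at one time bin
#'
#' For each selected trial, the representation is the voltage vector over
#' the chosen electrode set (9-dimensional for the peri-occipital and
#' peri-frontal presets) at the requested bin; the matrix holds Pearson
#' correlations between all trial pairs. On one variation condition of the
#' full design (16 objects x 3 presentations) it is 48 x 48.
#'
#' @param epochs One subject's `eeg_epochs`.
#' @param electrodes Electrode set (preset name or channel names).
#' @param trial_idx Integer indices of the trials to include.
#' @param time_ms Bin time (nearest bin is used).
#' @return List with `corr` (n x n correlation matrix), `trial_idx`,
#'   `electrodes`, `time_ms`. Zero-variance representations give NA
#'   rows/columns with a warning.
#' @export
similarity_matrix <- function(epochs, electrodes, trial_idx, time_ms) {
  stopifnot_epochs(epochs)
  chs <- electrode_preset(electrodes, epochs$channels)
  e <- match(chs, epochs$channels)
  tb <- which.min(abs(epochs$time - time_ms))
  M <- slice_trials(epochs$voltages, e, tb, trial_idx)  # dims x trials
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance representation(s); their ",
            "correlations are NA")
  }
  suppressWarnings(R <- stats::cor(M))
  diag(R) <- 1
  list(corr = R, trial_idx = trial_idx, electrodes = chs,
       time_ms = epochs$time[tb])
}

# lower-triangle vectorizations of the similarity matrix at every bin:
# n_pairs x n_bins matrix (n(n-1)/2 rows; 1128 for 48 trials)
sm_vector_series <- function(epochs, electrodes, trial_idx) {
  chs <- electrode_preset(electrodes, epochs$channels)
  e <- match(chs, epochs$channels)
  V <- epochs$voltages
  nb <- dim(V)[2]
  n <- length(trial_idx)
  lower <- lower.tri(matrix(0, n, n))
  out <- matrix(NA_real_, nrow = sum(lower), ncol = nb)
  for (t in seq_len(nb)) {
    R <- suppressWarnings(stats::cor(slice_trials(V, e, t, trial_idx)))
    out[, t] <- R[lower]
  }
  out
}

#' Average similarity matrices over a past window
#'
#' Entry-wise mean of the matrices in `[t + window[1], t + window[2]]` ms
#' (default t-130 to t-80, inclusive endpoints: 11 bins at 5 ms).
#'
#' @param sms List of similarity matrices (as from [similarity_matrix()])
#'   covering the epoch, or an `eeg_epochs` plus the arguments of
#'   [similarity_matrix()] via `...`.
#' @param time Time axis matching `sms`.
#' @param t Reference time (ms).
#' @param window Relative ms pair, default `c(-130, -80)`.
#' @return Entry-wise mean matrix.
#' @export
past_average <- function(sms, time, t, window = c(-130, -80)) {
  lo <- t + window[1]; hi <- t + window[2]
  if (lo < min(time) || hi > max(time)) {
    stop("past window [", lo, ", ", hi, "] ms falls outside the epoch")
  }
  idx <- which(time >= lo & time <= hi)
  mats <- lapply(sms[idx], function(s) if (is.list(s)) s$corr else s)
  Reduce(`+`, mats) / length(mats)
}

#' Partial correlation of two vectors given a third
#'
#' First-order partial correlation
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, the quantity the
#' information-flow curves are built from. NA (with a message) when either
#' conditioning correlation is +/-1.
#'
#' @param x,y,z Equal-length numeric vectors, length >= 3.
#' @return Scalar partial correlation.
#' @export
partial_corr <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z), length(x) >= 3L)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (is.na(den) || den <= 0) {
    message("partial correlation undefined: a conditioning correlation is +/-1")
    return(NA_real_)
  }
  (rxy - rxz * ryz) / sqrt(den)
}

# n_perm null partial correlations obtained by shuffling x (the time-t
# vectorized matrix) while y and z keep their structure; vectorized over
# permutations via cor() on a shuffled-column matrix
perm_partial <- function(x, y, z, n_perm) {
  n <- length(x)
  shM <- vapply(seq_len(n_perm), function(k) x[sample.int(n)], numeric(n))
  rxy <- as.vector(stats::cor(shM, y))
  rxz <- as.vector(stats::cor(shM, z))
  ryz <- stats::cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  out <- (rxy - rxz * ryz) / sqrt(den)
  out[den <= 0] <- NA_real_
  out
}

#' Feed-forward / feedback information flow between two electrode sets
#'
#' A simplified Granger causality on representational geometry: at each
#' bin t,
#' `FF(t) = pcor(SM(front, t), SM(back, t-past) ; SM(front, t-past))` and
#' `FB(t) = pcor(SM(back, t), SM(front, t-past) ; SM(back, t-past))`,
#' where SM is the lower-triangle vectorization of the similarity matrix
#' of the named electrode set and `t-past` averages the matrices over the
#' t-130..t-80 ms window. FF > 0 means the posterior past adds predictive
#' information about the current anterior geometry beyond the anterior
#' past (feed-forward transfer); FB is the mirror image. Flows are
#' reported for every bin whose full past window lies inside the epoch.
#'
#' The permutation null shuffles the vectorized entries of the time-t
#' matrix only (preserving the conditioning structure), recomputes both
#' partial correlations, and thresholds the true values at the 95th
#' percentile of `n_perm` shuffles per bin.
#'
#' @param epochs One subject's `eeg_epochs`.
#' @param trial_idx Trials forming the similarity matrices (e.g. the 48
#'   trials of one variation condition).
#' @param front,back Electrode sets (presets `"peri_frontal"` /
#'   `"peri_occipital"` by default).
#' @param past_window Relative ms pair averaged for the "past" matrices.
#' @param n_perm Permutations per bin (0 skips the null).
#' @param seed Integer seed for the shuffles.
#' @param level Null quantile for significance (0.95: rank 950 of 1000).
#' @param perm_bins_ms Optional bin times (ms) at which the permutation
#'   null is evaluated; `NULL` (default) evaluates it at every flow bin.
#' @return A `flow_result`: data frame-like list with `time_ms`, `ff`,
#'   `fb`, `diff`, per-bin null thresholds `ff_thresh`, `fb_thresh`,
#'   `diff_thresh`, and logical `sig_ff`, `sig_fb`, `sig_diff`.
#' @export
flow_curves <- function(epochs, trial_idx, front = "peri_frontal",
                        back = "peri_occipital", past_window = c(-130, -80),
                        n_perm = 1000, seed = 1L, level = 0.95,
                        perm_bins_ms = NULL) {
  stopifnot_epochs(epochs)
  time <- epochs$time
  sf <- sm_vector_series(epochs, front, trial_idx)
  sb <- sm_vector_series(epochs, back, trial_idx)
  bins <- which(time >= 0 & time + past_window[1] >= min(time))
  nb <- length(time)
  ff <- fb <- rep(NA_real_, nb)
  fft <- fbt <- dft <- rep(NA_real_, nb)
  sig_ff <- sig_fb <- sig_diff <- rep(NA, nb)
  set.seed(as.integer(seed))
  for (t in bins) {
    w <- which(time >= time[t] + past_window[1] & time <= time[t] + past_window[2])
    pf <- rowMeans(sf[, w, drop = FALSE])
    pb <- rowMeans(sb[, w, drop = FALSE])
    ff[t] <- partial_corr(sf[, t], pb, pf)
    fb[t] <- partial_corr(sb[, t], pf, pb)
    do_perm <- n_perm > 0 &&
      (is.null(perm_bins_ms) || any(abs(perm_bins_ms - time[t]) < 1e-9))
    if (do_perm) {
      null_ff <- perm_partial(sf[, t], pb, pf, n_perm)
      null_fb <- perm_partial(sb[, t], pf, pb, n_perm)
      r <- ceiling(level * n_perm)
      fft[t] <- sort(null_ff)[r]
      fbt[t] <- sort(null_fb)[r]
      dft[t] <- sort(null_ff - null_fb)[r]
      sig_ff[t] <- ff[t] > fft[t]
      sig_fb[t] <- fb[t] > fbt[t]
      sig_diff[t] <- (ff[t] - fb[t]) > dft[t]
    }
  }
  structure(list(time_ms = time, ff = ff, fb = fb, diff = ff - fb,
                 ff_thresh = fft, fb_thresh = fbt, diff_thresh = dft,
                 sig_ff = sig_ff, sig_fb = sig_fb, sig_diff = sig_diff,
                 front = electrode_preset(front, epochs$channels),
                 back = electrode_preset(back, epochs$channels),
                 past_window = past_window, n_perm = n_perm),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  ok <- !is.na(x$ff)
  cat("Information flow over ", sum(ok), " bins; mean FF-FB = ",
      signif(mean(x$diff[ok]), 3), "\n", sep = "")
  invisible(x)
}

#' Group-average information flow
#'
#' Computes [flow_curves()] per subject and averages FF, FB and their
#' permutation draws across subjects (each permutation index pairs one
#' independent shuffle per subject), so the null thresholds apply to the
#' group-mean curves.
#'
#' @param group List of `eeg_epochs`.
#' @param trial_idx_fn Function mapping one subject's trial table to the
#'   trial indices to use (designs are randomized per subject).
#' @inheritParams flow_curves
#' @return A `flow_result` for the group-mean curves.
#' @export
flow_curves_group <- function(group, trial_idx_fn, front = "peri_frontal",
                              back = "peri_occipital", past_window = c(-130, -80),
                              n_perm = 1000, seed = 1L, level = 0.95,
                              perm_bins_ms = NULL) {
  time <- group[[1]]$time
  nb <- length(time)
  ffs <- fbs <- matrix(NA_real_, length(group), nb)
  nulls_ff <- nulls_fb <- array(0, dim = c(max(n_perm, 1L), nb))
  bins_all <- NULL
  for (s in seq_along(group)) {
    epochs <- group[[s]]
    trial_idx <- trial_idx_fn(epochs$trials)
    sf <- sm_vector_series(epochs, front, trial_idx)
    sb <- sm_vector_series(epochs, back, trial_idx)
    bins <- which(time >= 0 & time + past_window[1] >= min(time))
    bins_all <- bins
    set.seed(as.integer((as.numeric(seed) * 7919 + s) %% 2147483647))
    for (t in bins) {
      w <- which(time >= time[t] + past_window[1] & time <= time[t] + past_window[2])
      pf <- rowMeans(sf[, w, drop = FALSE])
      pb <- rowMeans(sb[, w, drop = FALSE])
      ffs[s, t] <- partial_corr(sf[, t], pb, pf)
      fbs[s, t] <- partial_corr(sb[, t], pf, pb)
      do_perm <- n_perm > 0 &&
        (is.null(perm_bins_ms) || any(abs(perm_bins_ms - time[t]) < 1e-9))
      if (do_perm) {
        nulls_ff[, t] <- nulls_ff[, t] + perm_partial(sf[, t], pb, pf, n_perm)
        nulls_fb[, t] <- nulls_fb[, t] + perm_partial(sb[, t], pf, pb, n_perm)
      }
    }
  }
  ns <- length(group)
  ff <- colMeans(ffs); fb <- colMeans(fbs)
  fft <- fbt <- dft <- rep(NA_real_, nb)
  sig_ff <- sig_fb <- sig_diff <- rep(NA, nb)
  if (n_perm > 0) {
    r <- ceiling(level * n_perm)
    pbins <- if (is.null(perm_bins_ms)) bins_all else {
      bins_all[vapply(bins_all, function(t) any(abs(perm_bins_ms - time[t]) < 1e-9), NA)]
    }
    for (t in pbins) {
      nf <- nulls_ff[, t] / ns; nbk <- nulls_fb[, t] / ns
      fft[t] <- sort(nf)[r]; fbt[t] <- sort(nbk)[r]
      dft[t] <- sort(nf - nbk)[r]
      sig_ff[t] <- ff[t] > fft[t]
      sig_fb[t] <- fb[t] > fbt[t]
      sig_diff[t] <- (ff[t] - fb[t]) > dft[t]
    }
  }
  structure(list(time_ms = time, ff = ff, fb = fb, diff = ff - fb,
                 ff_thresh = fft, fb_thresh = fbt, diff_thresh = dft,
                 sig_ff = sig_ff, sig_fb = sig_fb, sig_diff = sig_diff,
                 front = electrode_preset(front, group[[1]]$channels),
                 back = electrode_preset(back, group[[1]]$channels),
                 past_window = past_window, n_perm = n_perm,
                 per_subject_ff = ffs, per_subject_fb = fbs),
            class = "flow_result")
}

#' Trials of one variation condition
#'
#' Helper selecting the 16-object x 3-presentation subset (48 trials at
#' the full design) of a single variation condition, the stimulus subset
#' the 48 x 48 similarity matrices are built from.
#'
#' @param trials Trial table of one subject.
#' @param type Variation dimension.
#' @param level Level (1-3).
#' @return Integer trial indices.
#' @export
variation_condition_trials <- function(trials, type = "size", level = 1L) {
  which(trials$variation_type == type & trials$variation_level == level)
}
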