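#' FDR correction of a p-value vector
#'
#' Benjamini-Hochberg step-up by default (deterministic, parameter-free);
#' `method = "storey"` gives a pi0-estimating positive-FDR variant in the
#' style of MATLAB's `mafdr` default (q-values may therefore be smaller
#' than BH when most hypotheses look null). Both enforce monotonicity of
#' the step-up. NaN/NA p-values propagate as NA with a warning.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.5))  # 0.04 0.04 0.04 0.50
#' @export
fdr_correct <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (anyNA(p)) warning("NA p-values propagate to NA q-values")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  if (method == "BH") {
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
  } else {
    q[ok] <- storey_qvalue(p[ok])
  }
  q
}

# Storey-style q-values: pi0 estimated from the fraction of p-values above
# lambda, then pi0-scaled BH step-up (lambda fixed at 0.5, the common
# plug-in). Reduces to BH when pi0 = 1.
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  if (m == 1L) return(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / m  # all p below lambda; keep the estimate positive
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Per-bin signed-rank test of decodability against the pre-stimulus level
#'
#' For each subject the reference is their own mean value over the
#' baseline window (before any baseline subtraction). Every post-stimulus
#' bin is then tested across subjects with a two-sided Wilcoxon signed-rank
#' test of the per-subject differences against zero, and the per-bin
#' p-values are FDR-corrected across the tested bins. Bins where every
#' subject's difference is exactly zero are degenerate and get p = 1.
#'
#' @param curves List of per-subject `decod_curve`s (not baseline
#'   corrected: the test subtracts each subject's own baseline), or a
#'   subjects x bins matrix via `values`/`time`.
#' @param values,time Alternative matrix interface.
#' @param baseline_window ms pair; bins with `time` in `[start, 0)`.
#' @param alpha Significance level applied to the q-values.
#' @param method FDR method, see [fdr_correct()].
#' @param include_prestim Also test pre-stimulus bins? Default tests only
#'   bins at `time >= 0`; untested bins carry NA.
#' @return Data frame: `time_ms`, `stat` (group mean difference), `p`, `q`,
#'   `significant`.
#' @export
signed_rank_vs_baseline <- function(curves = NULL, values = NULL, time = NULL,
                                    baseline_window = c(-200, 0), alpha = 0.05,
                                    method = "BH", include_prestim = FALSE) {
  if (is.null(values)) {
    g <- group_curves(curves)
    values <- g$values; time <- g$time
  }
  stopifnot(is.matrix(values), length(time) == ncol(values))
  if (nrow(values) < 5L) stop("signed-rank needs >= 5 subjects")
  bl <- baseline_bins(time, baseline_window)
  if (length(bl) == 0L) stop("no bins inside the baseline window")
  ref <- rowMeans(values[, bl, drop = FALSE])
  test_bins <- if (include_prestim) seq_along(time) else which(time >= 0)
  p <- rep(NA_real_, length(time))
  stat <- rep(NA_real_, length(time))
  for (t in test_bins) {
    d <- values[, t] - ref
    stat[t] <- mean(d)
    p[t] <- wilcoxon_signed_rank_p(d)
  }
  q <- rep(NA_real_, length(time))
  q[test_bins] <- fdr_correct(p[test_bins], method = method)
  data.frame(time_ms = time, stat = stat, p = p, q = q,
             significant = !is.na(q) & q < alpha)
}

# Two-sided signed-rank p for one-sample differences; exact when n <= 50
# and no ties/zeros (wilcox.test's own policy), p = 1 when all diffs are 0.
wilcoxon_signed_rank_p <- function(d) {
  d <- d[!is.na(d)]
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "two.sided")$p.value)
}

#' Detection latency and peak of a group decodability curve
#'
#' Latency is the first post-stimulus bin at which the curve *rises* to
#' significance: q below alpha with a positive group difference from
#' baseline (bins significantly below baseline do not count as detected
#' information; NA when no bin qualifies). The peak is the argmax of the
#' group-mean curve over post-stimulus bins, earliest bin on ties.
#'
#' @param curve Group-mean values (numeric vector) or a `decod_curve`.
#' @param trace Output of [signed_rank_vs_baseline()] on the same axis.
#' @param time Time axis if `curve` is a plain vector.
#' @return List with `latency_ms`, `peak_ms`, `peak_value`.
#' @export
latency_peak <- function(curve, trace, time = NULL) {
  if (inherits(curve, "decod_curve")) { time <- curve$time; curve <- curve$values }
  if (length(curve) != nrow(trace) || any(time != trace$time_ms)) {
    stop("significance trace is not aligned to the curve")
  }
  post <- which(time >= 0)
  rising <- if (is.null(trace$stat)) TRUE else trace$stat[post] > 0
  sig <- post[trace$significant[post] %in% TRUE & rising]
  latency <- if (length(sig)) time[sig[1]] else NA_real_
  pk <- post[which.max(curve[post])]
  list(latency_ms = latency, peak_ms = time[pk], peak_value = curve[pk])
}

#' Sliding-window correlation between two curves
#'
#' Pearson correlation over a trailing window ending at each bin (50 ms =
#' 10 bins at 5 ms resolution; the window never uses future samples). Bins
#' whose window is incomplete or has zero variance in either curve yield
#' NA. Given per-subject matrices, correlations are computed per subject
#' and group-tested per bin (two-sided signed-rank of the Fisher-stable r
#' values against 0); given plain vectors, the per-window correlation test
#' p-value is used. p-values are FDR-corrected across defined bins.
#'
#' @param a,b Numeric vectors (e.g. group-mean curves) or subjects x bins
#'   matrices on a common time axis.
#' @param time Time axis (ms).
#' @param window_ms Trailing window length; must be a multiple of the bin
#'   width.
#' @param alpha Significance level on q-values.
#' @return Data frame `time_ms`, `r` (group mean r when per-subject), `p`,
#'   `q`, `significant`.
#' @export
sliding_correlation <- function(a, b, time, window_ms = 50, alpha = 0.05) {
  bw <- time[2] - time[1]
  k <- window_ms / bw
  if (abs(k - round(k)) > 1e-9) stop("window_ms must be a multiple of the bin width")
  k <- as.integer(round(k))
  per_subject <- is.matrix(a)
  if (per_subject) stopifnot(is.matrix(b), all(dim(a) == dim(b)))
  nb <- length(time)
  r <- rep(NA_real_, nb); p <- rep(NA_real_, nb)
  win_r <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }
  for (t in seq_len(nb)) {
    if (t < k) next
    w <- (t - k + 1L):t
    if (per_subject) {
      rs <- vapply(seq_len(nrow(a)), function(s) win_r(a[s, w], b[s, w]), 0)
      r[t] <- mean(rs, na.rm = TRUE)
      if (all(is.na(rs))) next
      p[t] <- wilcoxon_signed_rank_p(rs[!is.na(rs)])
    } else {
      r[t] <- win_r(a[w], b[w])
      if (!is.na(r[t])) {
        p[t] <- suppressWarnings(stats::cor.test(a[w], b[w])$p.value)
      }
    }
  }
  q <- rep(NA_real_, nb)
  def <- !is.na(p)
  q[def] <- fdr_correct(p[def])
  data.frame(time_ms = time, r = r, p = p, q = q,
             significant = !is.na(q) & q < alpha)
}

#' Category curves at decreasing cluster sizes
#'
#' Down-samples the per-category trial clusters to each requested size,
#' recomputes the pooled pair-averaged category curve, and averages over
#' `n_reps` random draws; reports sliding correlations between each pair of
#' sizes on the averaged curves. A size equal to the full cluster size uses
#' all trials (a single deterministic "draw").
#'
#' @param epochs One subject's `eeg_epochs`.
#' @param sizes Cluster sizes (trials per category) to test.
#' @param n_reps Random draws per size.
#' @param seed Integer seed.
#' @param electrodes Electrode set.
#' @param window_ms Sliding-correlation window.
#' @return List with `curves` (one averaged `decod_curve` per size) and
#'   `correlations` (named list of sliding-correlation data frames for each
#'   size pair).
#' @export
subsample_category_curves <- function(epochs, sizes = c(144, 100, 48, 12, 3),
                                      n_reps = 100, seed = 1L,
                                      electrodes = "all", window_ms = 50) {
  stopifnot_epochs(epochs)
  trials <- epochs$trials
  avail <- min(table(trials$category))
  if (any(sizes > avail)) {
    stop("requested size exceeds the ", avail, " trials available per category")
  }
  chs <- electrode_preset(electrodes, epochs$channels)
  e <- match(chs, epochs$channels)
  V <- epochs$voltages
  nb <- dim(V)[2]
  pairs <- utils::combn(CATEGORIES, 2, simplify = FALSE)
  cat_idx <- lapply(CATEGORIES, function(cc) which(trials$category == cc))
  names(cat_idx) <- CATEGORIES
  set.seed(as.integer(seed))
  curves <- list()
  for (sz in sizes) {
    reps <- if (sz == avail) 1L else n_reps
    acc <- numeric(nb)
    for (r in seq_len(reps)) {
      sub_idx <- lapply(cat_idx, function(ix) {
        if (sz == length(ix)) ix else ix[sample.int(length(ix), sz)]
      })
      for (pr in pairs) {
        ia <- sub_idx[[pr[1]]]; ib <- sub_idx[[pr[2]]]
        for (t in seq_len(nb)) {
          acc[t] <- acc[t] + dprime(t(slice_trials(V, e, t, ia)),
                                    t(slice_trials(V, e, t, ib)))
        }
      }
    }
    vals <- apply_baseline(acc / (reps * length(pairs)), epochs$time)
    curves[[paste0("n", sz)]] <- new_curve(vals, epochs$time,
                                           paste0("category-average@", sz),
                                           "pooled", chs, TRUE)
  }
  cors <- list()
  cmb <- utils::combn(names(curves), 2, simplify = FALSE)
  for (pp in cmb) {
    cors[[paste(pp, collapse = "_vs_")]] <- sliding_correlation(
      curves[[pp[1]]]$values, curves[[pp[2]]]$values, epochs$time, window_ms)
  }
  list(curves = curves, correlations = cors)
}
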