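# brute-force BH step-up: q_i = min over j with p_j >= p_i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[o[i]] <- min(pmin(1, sorted[i:m] * m / (i:m)))
  }
  q
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
signed_rank_exact_p <- function(d) {
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

test_that("BH correction matches the hand example and a brute-force oracle", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_correct(0.123), 0.123)
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  set.seed(12)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_correct(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_warning(q <- fdr_correct(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(q[2]) && !anyNA(q[-2]))
})

test_that("the Storey variant scales BH by the null-fraction estimate", {
  set.seed(4)
  p <- c(runif(50), runif(10, 0, 1e-3))
  qs <- fdr_correct(p, method = "storey")
  qb <- fdr_correct(p, method = "BH")
  expect_true(all(qs <= qb + 1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("the signed-rank test agrees with exact sign enumeration", {
  set.seed(9)
  for (n in c(6, 8, 10)) {
    for (i in 1:20) {
      d <- round(rnorm(n, mean = 0.3), 3)
      if (any(d == 0) || anyDuplicated(abs(d))) next  # exact path needs no ties
      expect_equal(eegmvpa:::wilcoxon_signed_rank_p(d), signed_rank_exact_p(d),
                   tolerance = 1e-12)
    }
  }
  # degenerate all-zero differences
  expect_equal(eegmvpa:::wilcoxon_signed_rank_p(rep(0, 8)), 1)
})

test_that("identical pre and post values yield no significant bins", {
  time <- seq(-100, 95, by = 5)
  vals <- matrix(rep(rnorm(10), times = length(time)), nrow = 10)
  tr <- signed_rank_vs_baseline(values = vals, time = time,
                                baseline_window = c(-100, 0))
  expect_false(any(tr$significant, na.rm = TRUE))
})

test_that("latency is the first significant bin and peak the curve argmax", {
  time <- seq(-100, 95, by = 5)
  curve <- dnorm(time, mean = 50, sd = 20)
  trace <- data.frame(time_ms = time, stat = curve, p = 1, q = 1,
                      significant = time >= 85)
  lp <- latency_peak(curve, trace, time = time)
  expect_equal(lp$latency_ms, 85)
  expect_equal(lp$peak_ms, 50)
  # monotone rising curve peaks at the last bin
  trace$significant <- FALSE
  lp2 <- latency_peak(seq_along(time), trace, time = time)
  expect_true(is.na(lp2$latency_ms))
  expect_equal(lp2$peak_ms, max(time))
})

test_that("sliding correlation honors affine relations and self-identity", {
  time <- seq(0, 495, by = 5)
  a <- sin(time / 40) + time / 200
  sc <- sliding_correlation(a, 2 * a + 1, time, window_ms = 50)
  defined <- !is.na(sc$r)
  expect_true(any(defined))
  expect_true(all(abs(sc$r[defined] - 1) < 1e-10))
  sc_neg <- sliding_correlation(a, -a, time, window_ms = 50)
  expect_true(all(abs(sc_neg$r[!is.na(sc_neg$r)] + 1) < 1e-10))
  sc_self <- sliding_correlation(a, a, time, window_ms = 50)
  expect_true(all(abs(sc_self$r[!is.na(sc_self$r)] - 1) < 1e-12))
  expect_error(sliding_correlation(a, a, time, window_ms = 12), "multiple")
})

test_that("phase-shifted bumps correlate negatively during the offset span", {
  time <- seq(0, 495, by = 5)
  a <- exp(-(time - 200)^2 / (2 * 30^2))
  b <- exp(-(time - 260)^2 / (2 * 30^2))  # shifted by one bump sd span
  sc <- sliding_correlation(a, b, time, window_ms = 50)
  # while a falls and b rises the windows anti-correlate
  mid <- sc$time_ms >= 230 & sc$time_ms <= 260
  expect_true(any(sc$r[mid] < -0.5, na.rm = TRUE))
})

test_that("subsampled category curves reproduce the full curve at full size", {
  cfg <- synth_config(n_subjects = 1, channel_names = paste0("CH", 1:8),
                      sfreq_raw = 200, epoch_window = c(-100, 199),
                      noise_sd = 1, ar_coeff = 0.77, n_reps = 1)
  ep <- generate_subject(cfg, 1L, seed = 14)
  # 48 trials per category available here; request full size and a subset
  res <- subsample_category_curves(ep, sizes = c(48, 12), n_reps = 5,
                                   seed = 3)
  expect_named(res$curves, c("n48", "n12"))
  full <- average_pairs(decode_all_pairs(ep, "category", baseline = TRUE))
  expect_equal(res$curves$n48$values, full$values, tolerance = 1e-12)
  res2 <- subsample_category_curves(ep, sizes = c(48, 12), n_reps = 5,
                                    seed = 3)
  expect_identical(res$curves$n12$values, res2$curves$n12$values)
  expect_error(subsample_category_curves(ep, sizes = 100), "exceeds")
})
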