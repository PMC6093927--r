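# partial correlation via the regression-residual route: correlate the
# residuals of x ~ z and y ~ z
pcor_residual_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

test_that("partial correlation matches the closed form and the residual oracle", {
  # closed-form arithmetic: (0.8 - 0.25) / 0.75
  r <- (0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(r, 0.55 / 0.75)
  set.seed(5)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    expect_equal(partial_corr(x, y, z), pcor_residual_oracle(x, y, z),
                 tolerance = 1e-10)
  }
  # z uncorrelated with x and y reduces to the plain correlation: construct
  # exact zero correlations by orthogonalization
  set.seed(6)
  n <- 40
  z <- rnorm(n)
  x <- stats::residuals(stats::lm(rnorm(n) ~ z))
  y0 <- stats::residuals(stats::lm(rnorm(n) ~ z))
  expect_equal(partial_corr(x, y0, z), cor(x, y0), tolerance = 1e-10)
  # perfectly conditioning correlation is undefined
  expect_message(out <- partial_corr(z, rnorm(n), z), "undefined")
  expect_true(is.na(out))
})

test_that("similarity matrices hold trial-pair Pearson correlations", {
  cfg <- lagged_cfg()
  ep <- generate_subject(cfg, 1L, seed = 3)
  sm <- similarity_matrix(ep, "peri_occipital", seq_len(48), time_ms = 150)
  expect_equal(dim(sm$corr), c(48L, 48L))
  expect_true(isSymmetric(sm$corr))
  expect_equal(diag(sm$corr), rep(1, 48))
  # closed-form check on three hand-picked trials
  e <- match(electrode_preset("peri_occipital"), ep$channels)
  tb <- which.min(abs(ep$time - 150))
  v1 <- ep$voltages[e, tb, 1]; v2 <- ep$voltages[e, tb, 2]
  expect_equal(sm$corr[1, 2], cor(v1, v2), tolerance = 1e-12)
})

test_that("past averaging covers 11 bins with inclusive endpoints", {
  time <- seq(-200, 395, by = 5)
  idx <- which(time >= 200 - 130 & time <= 200 - 80)
  expect_length(idx, 11L)  # (130 - 80)/5 + 1
  mats <- lapply(seq_along(time), function(i) matrix(i, 2, 2))
  avg <- past_average(mats, time, t = 200)
  expect_equal(avg, matrix(mean(idx), 2, 2))
  # constant series -> same matrix; alternating -> hand-computed mean
  cst <- lapply(seq_along(time), function(i) matrix(3, 2, 2))
  expect_equal(past_average(cst, time, t = 100), matrix(3, 2, 2))
  alt <- lapply(seq_along(time), function(i) matrix(ifelse(i %% 2, 1, 5), 2, 2))
  w <- ifelse(idx %% 2, 1, 5)
  expect_equal(past_average(alt, time, t = 200), matrix(mean(w), 2, 2))
  expect_error(past_average(mats, time, t = -80), "outside the epoch")
})

test_that("feed-forward and feedback swap exactly when the regions swap", {
  cfg <- lagged_cfg()
  ep <- generate_subject(cfg, 1L, seed = 11)
  fwd <- flow_curves(ep, seq_len(48), front = "peri_frontal",
                     back = "peri_occipital", n_perm = 0)
  swp <- flow_curves(ep, seq_len(48), front = "peri_occipital",
                     back = "peri_frontal", n_perm = 0)
  ok <- !is.na(fwd$ff)
  expect_equal(fwd$ff[ok], swp$fb[ok], tolerance = 1e-12)
  expect_equal(fwd$fb[ok], swp$ff[ok], tolerance = 1e-12)
})

test_that("flow values are invariant to consistent stimulus reordering", {
  cfg <- lagged_cfg()
  ep <- generate_subject(cfg, 1L, seed = 12)
  set.seed(1)
  perm <- sample(48)
  a <- flow_curves(ep, seq_len(48), n_perm = 0)
  b <- flow_curves(ep, seq_len(48)[perm], n_perm = 0)
  ok <- !is.na(a$ff)
  expect_equal(a$ff[ok], b$ff[ok], tolerance = 1e-10)
  expect_equal(a$fb[ok], b$fb[ok], tolerance = 1e-10)
})

test_that("a planted posterior-to-frontal lag is recovered as feed-forward flow", {
  ep <- generate_subject(lagged_cfg(lag_ms = 100), 1L, seed = 7)
  fl <- flow_curves(ep, seq_len(48), n_perm = 200, seed = 3,
                    perm_bins_ms = seq(230, 270, 5))
  w <- which(fl$time_ms >= 230 & fl$time_ms <= 270)
  expect_gt(mean(fl$diff[w]), 0)
  expect_true(any(fl$sig_diff[w]))
  # reversed lag: the same window shows feedback dominance
  epr <- generate_subject(lagged_cfg(lag_ms = 100, reverse = TRUE), 1L, seed = 7)
  flr <- flow_curves(epr, seq_len(48), n_perm = 200, seed = 3,
                     perm_bins_ms = seq(230, 270, 5))
  expect_lt(mean(flr$diff[w]), 0)
})

test_that("permutation thresholds sit at the 95th null rank and are seeded", {
  ep <- generate_subject(lagged_cfg(), 1L, seed = 9)
  a <- flow_curves(ep, seq_len(48), n_perm = 100, seed = 4,
                   perm_bins_ms = c(250))
  b <- flow_curves(ep, seq_len(48), n_perm = 100, seed = 4,
                   perm_bins_ms = c(250))
  expect_identical(a$ff_thresh, b$ff_thresh)
  tb <- which(!is.na(a$ff_thresh))
  expect_length(tb, 1L)
  expect_true(is.finite(a$ff_thresh[tb]))
})
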