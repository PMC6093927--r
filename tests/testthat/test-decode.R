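test_that("pair averaging is a pointwise mean and validates time axes", {
  mk <- function(vals, time = 1:3) {
    structure(list(values = vals, time = time, contrast = "x",
                   scheme = "pooled", electrodes = "CH1",
                   baseline_corrected = FALSE, baseline_window = c(-200, 0)),
              class = "decod_curve")
  }
  # car-average from three constant pair curves 1, 2, 3 -> constant 2
  avg <- average_pairs(list(mk(rep(1, 3)), mk(rep(2, 3)), mk(rep(3, 3))))
  expect_equal(avg$values, rep(2, 3))
  # identical inputs -> identical output
  expect_equal(average_pairs(list(mk(1:3), mk(1:3)))$values, 1:3)
  expect_error(average_pairs(list(mk(1:3), mk(1:3, time = 2:4))), "mismatched")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  cfg <- null_cfg(n_subjects = 1)
  ep <- generate_subject(cfg, 1L, seed = 8)
  cv <- decode_timecourse(ep, contrast_category("car", "face"),
                          baseline = TRUE, baseline_window = c(-100, 0))
  bl <- cv$time >= -100 & cv$time < 0
  expect_lt(abs(mean(cv$values[bl])), 1e-10)
})

test_that("per-condition and pooled schemes agree when the effect is uniform", {
  # the planted car effect is identical in every variation condition, so
  # stratified and pooled curves estimate the same signal
  cfg <- synth_config(n_subjects = 1, sfreq_raw = 200,
                      epoch_window = c(-100, 199), noise_sd = 0.5,
                      ar_coeff = 0.5, n_reps = 2,
                      effects = list(effect_spec("category", "car",
                                                 spatial_pattern = "global",
                                                 onset_ms = 100, width_ms = 40,
                                                 amplitude = 4)))
  ep <- generate_subject(cfg, 1L, seed = 13)
  pooled <- decode_timecourse(ep, contrast_category("car", "face"),
                              scheme = "pooled", baseline = FALSE,
                              baseline_window = c(-100, 0))
  strat <- decode_timecourse(ep, contrast_category("car", "face"),
                             scheme = "per_condition", baseline = FALSE,
                             baseline_window = c(-100, 0))
  pk <- which.max(pooled$values)
  expect_true(abs(pooled$time[pk] - 100) <= 10)
  expect_true(abs(strat$time[which.max(strat$values)] - 100) <= 10)
  # peak heights agree up to the stratum-size Monte-Carlo error
  expect_lt(abs(pooled$values[pk] - strat$values[pk]) /
              max(pooled$values[pk], 1e-9), 0.5)
})

test_that("variation contrasts stratify by object in the per-condition scheme", {
  cfg <- synth_config(n_subjects = 1, sfreq_raw = 200,
                      epoch_window = c(-100, 99), n_reps = 3)
  ep <- generate_subject(cfg, 1L, seed = 4)
  cv <- decode_timecourse(ep, contrast_variation("size", 1, 2),
                          scheme = "per_condition", baseline = FALSE,
                          baseline_window = c(-100, 0))
  expect_length(cv$values, 40L)
  expect_true(all(is.finite(cv$values)))
})

test_that("scalp maps return one value per electrode and respect the window", {
  cfg <- planted_cfg(n_subjects = 1)
  ep <- generate_subject(cfg, 1L, seed = 2)
  m <- scalp_map(ep, contrast_category("car", "face"), center_ms = 150)
  expect_length(m, 31L)
  expect_named(m, montage_channels())
  expect_error(scalp_map(ep, contrast_category("car", "face"),
                         center_ms = 290), "exceeds the epoch")
})

test_that("monotonically larger planted amplitudes never reduce the peak d-prime", {
  amps <- c(0.5, 1, 2, 4, 8)
  peaks <- vapply(amps, function(a) {
    cfg <- synth_config(n_subjects = 1, sfreq_raw = 200,
                        epoch_window = c(-100, 199), noise_sd = 1,
                        ar_coeff = 0.77, n_reps = 1,
                        effects = list(effect_spec("category", "car",
                                                   spatial_pattern = "global",
                                                   onset_ms = 100,
                                                   width_ms = 30,
                                                   amplitude = a)))
    ep <- generate_subject(cfg, 1L, seed = 31)  # same noise seed throughout
    cv <- decode_timecourse(ep, contrast_category("car", "face"),
                            baseline = FALSE, baseline_window = c(-100, 0))
    max(cv$values[cv$time >= 0])
  }, 0)
  expect_gt(cor(amps, peaks, method = "spearman"), 0.95)
})

test_that("label-ignorant subsampled curves are flat and reproducible", {
  cfg <- null_cfg(n_subjects = 1)
  ep <- generate_subject(cfg, 1L, seed = 17)
  c1 <- random_subsample_curve(ep, n_per_cluster = 24, n_reps = 20, seed = 5,
                               baseline_window = c(-100, 0))
  c2 <- random_subsample_curve(ep, n_per_cluster = 24, n_reps = 20, seed = 5,
                               baseline_window = c(-100, 0))
  expect_identical(c1$values, c2$values)
  # null data: post-stimulus mean stays at the baseline level
  post <- c1$time >= 0
  expect_lt(abs(mean(c1$values[post])), 0.1)
  expect_error(random_subsample_curve(ep, n_per_cluster = 60), "exceeds")
})
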