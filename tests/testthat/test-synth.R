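test_that("binning averages non-overlapping 5-sample blocks with centered times", {
  # hand-computed means: [1,2,3,4,5] -> 3, [10 x5] -> 10
  raw <- array(c(1, 2, 3, 4, 5, 10, 10, 10, 10, 10), dim = c(1, 10, 1))
  ep <- bin_epochs(raw, sfreq_raw = 1000, epoch_window = c(0, 9))
  expect_equal(as.vector(ep$voltages), c(3, 10))
  expect_equal(ep$time, c(2, 7))  # first sample time + 2 ms

  # constant input stays constant
  cst <- array(7.5, dim = c(2, 15, 3))
  expect_true(all(bin_epochs(cst, 1000, c(0, 14))$voltages == 7.5))

  # 1005 raw samples over -200..804 ms -> 201 bins
  big <- array(0, dim = c(1, 1005, 1))
  ep2 <- bin_epochs(big, 1000, c(-200, 804))
  expect_equal(dim(ep2$voltages)[2], 201L)
  expect_equal(ep2$time[1], -198)
  expect_equal(diff(ep2$time)[1], 5)

  expect_error(bin_epochs(array(0, dim = c(1, 7, 1)), 1000, c(0, 6)),
               "not divisible")
})

test_that("the generator reproduces the full recording geometry", {
  cfg <- synth_config(n_subjects = 1)
  ep <- generate_subject(cfg, 1L, seed = 5)
  expect_equal(dim(ep$voltages), c(31L, 201L, 576L))
  expect_equal(nrow(ep$trials), 576L)
  expect_equal(ep$channels, montage_channels())
  expect_true(all(diff(ep$time) == 5))
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- null_cfg(n_subjects = 1)
  a <- generate_subject(cfg, 2L, seed = 99)
  b <- generate_subject(cfg, 2L, seed = 99)
  expect_identical(a$voltages, b$voltages)
  expect_identical(a$trials, b$trials)
  c <- generate_subject(cfg, 2L, seed = 100)
  expect_false(identical(a$voltages, c$voltages))
})

test_that("planted effects peak at the requested latency and region", {
  cfg <- planted_cfg(amplitude = 8, onset_ms = 150, width_ms = 25,
                     n_subjects = 3)
  group <- generate_group(cfg, seed = 21)
  curves <- group_category_curves(group, baseline = TRUE)
  g <- group_curves(curves)
  pk <- g$time[which.max(g$mean)]
  expect_true(abs(pk - 150) <= 10)  # within two bins of the planted peak

  # effect confined to the occipital pattern: occipital channels dominate
  m <- rowMeans(sapply(group, function(ep) {
    scalp_map(ep, contrast_category("car", "face"), center_ms = 150)
  }))
  occ <- electrode_preset("peri_occipital")
  expect_true(names(which.max(m)) %in% occ)
})

test_that("unknown effect levels are rejected by name", {
  des <- generate_design()
  sub <- des[des$category %in% c("car", "face"), ]
  cfg <- synth_config(n_subjects = 1, sfreq_raw = 200,
                      epoch_window = c(-100, 99), n_reps = 1, design = sub,
                      effects = list(effect_spec("category", "animal",
                                                 onset_ms = 50, width_ms = 20,
                                                 amplitude = 1)))
  expect_error(generate_subject(cfg, 1L, 1), "animal")
})

test_that("the AR(1) noise is temporally autocorrelated at the configured strength", {
  cfg <- synth_config(n_subjects = 1, channel_names = "CH1", sfreq_raw = 1000,
                      epoch_window = c(0, 999), noise_sd = 1, ar_coeff = 0.9,
                      n_reps = 1, design = generate_design()[1:10, ])
  set.seed(1)
  raw_ac <- replicate(5, {
    ep <- generate_subject(cfg, 1L, seed = sample.int(1e6, 1))
    # at 5 ms bins the AR(1) lag-1 autocorrelation is attenuated but positive
    mean(apply(ep$voltages[1, , ], 2, function(x) {
      stats::cor(x[-1], x[-length(x)])
    }))
  })
  expect_true(all(raw_ac > 0.3))
})
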