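# Small simulated datasets shared across tests. All are generated in code;
# reduced sampling rates (200 Hz = one raw sample per 5 ms bin) and design
# subsets keep them fast without changing the analysis geometry.

# two-category subset, 8 generic channels: cheap null data for calibration
null_cfg <- function(n_subjects = 10, n_channels = 8,
                     epoch_window = c(-100, 199)) {
  des <- generate_design()
  synth_config(
    n_subjects = n_subjects,
    channel_names = paste0("CH", seq_len(n_channels)),
    sfreq_raw = 200, epoch_window = epoch_window,
    noise_sd = 1, ar_coeff = 0.77, n_reps = 1,
    design = des[des$category %in% c("car", "face"), ])
}

# full montage, planted occipital car effect peaking at onset_ms
planted_cfg <- function(amplitude = 5, onset_ms = 150, width_ms = 25,
                        n_subjects = 10) {
  synth_config(
    n_subjects = n_subjects,
    sfreq_raw = 200, epoch_window = c(-200, 299),
    noise_sd = 1, ar_coeff = 0.77, n_reps = 1,
    effects = list(effect_spec("category", "car",
                               spatial_pattern = "occipital",
                               onset_ms = onset_ms, width_ms = width_ms,
                               amplitude = amplitude)))
}

# per-category occipital patterns propagating to matched frontal patterns
# after lag_ms: the substrate for information-flow direction recovery.
# reverse = TRUE plants the frontal pattern first instead.
lagged_cfg <- function(lag_ms = 100, amplitude = 5, reverse = FALSE,
                       onset_ms = 150, width_ms = 30) {
  des <- generate_design()
  sub <- des[des$variation_type == "size" & des$variation_level == 1, ]
  occ <- electrode_preset("peri_occipital")
  fro <- electrode_preset("peri_frontal")
  cats <- c("animal", "car", "face", "plane")
  effs <- lapply(seq_along(cats), function(i) {
    set.seed(1000L + i)  # fixed per-category 9-channel patterns
    w <- stats::rnorm(9)
    first <- stats::setNames(w, if (reverse) fro else occ)
    second <- stats::setNames(w, if (reverse) occ else fro)
    effect_spec("category", cats[i], spatial_pattern = first,
                onset_ms = onset_ms, width_ms = width_ms,
                amplitude = amplitude, lag_ms = lag_ms, lag_pattern = second)
  })
  synth_config(n_subjects = 1, sfreq_raw = 200, epoch_window = c(-200, 599),
               noise_sd = 1, ar_coeff = 0.77, effects = effs, design = sub)
}

# every design dimension carries an effect; disjoint = one channel group
# per dimension, shared = everything on the occipital group
two_regime_cfg <- function(disjoint) {
  region_sets <- list(
    category = electrode_preset("peri_occipital"),
    size = electrode_preset("peri_frontal"),
    position = c("FT7", "FC3", "FCZ", "FC4", "FT8"),
    pose = c("T7", "C3", "CZ", "C4", "T8"),
    lighting = c("CP3", "CPZ", "CP4"))
  cats <- c("animal", "car", "face", "plane")
  effs <- list()
  for (i in seq_along(cats)) {
    effs[[length(effs) + 1L]] <- effect_spec(
      "category", cats[i],
      spatial_pattern = stats::setNames(rep(i, 9), region_sets$category),
      onset_ms = 100, width_ms = 40, amplitude = 4)
  }
  for (vt in c("size", "position", "pose", "lighting")) {
    for (lv in 1:3) {
      chs <- if (disjoint) region_sets[[vt]] else region_sets$category
      effs[[length(effs) + 1L]] <- effect_spec(
        "variation", lv, variation_type = vt,
        spatial_pattern = stats::setNames(rep(lv, length(chs)), chs),
        onset_ms = 100, width_ms = 40, amplitude = 4)
    }
  }
  synth_config(n_subjects = 1, sfreq_raw = 200, epoch_window = c(-100, 199),
               noise_sd = 1, ar_coeff = 0.77, n_reps = 2, effects = effs)
}

# group category-average curves (uncorrected) for significance testing
group_category_curves <- function(group, baseline = FALSE) {
  lapply(group, function(ep) {
    average_pairs(decode_all_pairs(ep, "category", scheme = "pooled",
                                   baseline = baseline), "category-average")
  })
}
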