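#' Configuration for the synthetic epoched-EEG generator
#'
#' Describes one simulated recording: montage, raw sampling rate, epoch
#' window, AR(1) noise, and the list of planted effects. Defaults reproduce
#' the analysis geometry the pipeline expects: 31 channels, 1 kHz raw
#' sampling over -200..+804 ms so that 5-sample binning yields exactly 201
#' five-millisecond bins.
#'
#' Noise is an AR(1) process per channel at the raw rate: innovations are
#' Gaussian with standard deviation `noise_sd` (microvolts) and lag-one
#' coefficient `ar_coeff`; the first sample is drawn from the stationary
#' distribution. `shared_noise_sd > 0` adds one common AR(1) trace per trial
#' to every channel, inducing across-channel correlation as seen in real
#' scalp recordings.
#'
#' @param n_subjects Number of subjects a group simulation should produce.
#' @param channel_names Montage; defaults to the 31-channel 10-20 set.
#' @param sfreq_raw Raw sampling rate in Hz. Bins are always 5 ms wide, so
#'   `sfreq_raw` must be a multiple of 200; lower rates (e.g. 200 Hz, one
#'   raw sample per bin) make large calibration simulations affordable.
#' @param epoch_window Length-2 ms pair, start inclusive; the raw epoch
#'   covers `epoch_window[1]` up to (not including) `epoch_window[2] + 1` ms
#'   so the default (-200, 804) holds 1005 one-millisecond samples.
#' @param noise_sd Innovation SD of the per-channel AR(1) noise, microvolts.
#' @param ar_coeff AR(1) coefficient in `[0, 1)` at the raw rate.
#' @param shared_noise_sd Innovation SD of the common across-channel AR(1)
#'   component (0 disables it).
#' @param effects List of [effect_spec()] objects to plant.
#' @param n_reps Presentations per image (3 gives 576 trials per subject).
#' @param design Stimulus design table; subset it to simulate partial
#'   designs (e.g. one variation condition only).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 10L,
                         channel_names = montage_channels(),
                         sfreq_raw = 1000,
                         epoch_window = c(-200, 804),
                         noise_sd = 1,
                         ar_coeff = 0.95,
                         shared_noise_sd = 0,
                         effects = list(),
                         n_reps = 3L,
                         design = generate_design()) {
  stopifnot(noise_sd > 0, ar_coeff >= 0, ar_coeff < 1, shared_noise_sd >= 0,
            length(epoch_window) == 2L, epoch_window[1] < epoch_window[2])
  if (sfreq_raw %% 200 != 0) {
    stop("sfreq_raw must be a multiple of 200 Hz so 5 ms bins hold a whole ",
         "number of raw samples")
  }
  n_samples <- (epoch_window[2] - epoch_window[1] + 1) * sfreq_raw / 1000
  if (n_samples != round(n_samples)) stop("epoch_window does not align with sfreq_raw")
  structure(list(
    n_subjects = as.integer(n_subjects),
    channel_names = channel_names,
    sfreq_raw = sfreq_raw,
    epoch_window = epoch_window,
    noise_sd = noise_sd,
    ar_coeff = ar_coeff,
    shared_noise_sd = shared_noise_sd,
    effects = effects,
    n_reps = as.integer(n_reps),
    design = design
  ), class = "synth_config")
}

#' Specify one planted spatiotemporal effect
#'
#' An effect adds `amplitude * spatial_pattern[ch] * k(t)` to every trial
#' whose labels match, where `k(t)` is a raised-cosine (Hann) bump peaking
#' at `onset_ms` with support `onset_ms +/- width_ms`. The compact support
#' means the evoked difference is exactly zero outside that window, so
#' detection latencies are interpretable against ground truth.
#'
#' With `lag_ms` set, a second copy of the bump is added at
#' `onset_ms + lag_ms` using `lag_pattern`, emulating propagation of the
#' same condition information to a second scalp region (the substrate for
#' information-flow recovery tests).
#'
#' @param dimension `"category"` or `"variation"`.
#' @param level For categories, one of animal/car/face/plane; for
#'   variations, the level (1-3) of `variation_type`.
#' @param variation_type Required when `dimension = "variation"`.
#' @param spatial_pattern Per-channel weights (unitless), one per montage
#'   channel, or a preset name for [spatial_pattern()].
#' @param onset_ms,width_ms Peak time and half-support of the Hann bump, ms.
#' @param amplitude Peak amplitude in microvolts; must be >= 0.
#' @param lag_ms Optional propagation delay (ms, >= 0) for the lagged copy.
#' @param lag_pattern Per-channel weights (or preset name) for the lagged
#'   copy; required when `lag_ms` is given.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(dimension = c("category", "variation"), level,
                        variation_type = NULL,
                        spatial_pattern = "global",
                        onset_ms, width_ms, amplitude,
                        lag_ms = NULL, lag_pattern = NULL) {
  dimension <- match.arg(dimension)
  stopifnot(amplitude >= 0, width_ms > 0)
  if (dimension == "variation" && is.null(variation_type)) {
    stop("variation effects need a variation_type")
  }
  if (!is.null(lag_ms)) {
    stopifnot(lag_ms >= 0)
    if (is.null(lag_pattern)) stop("lag_ms given without lag_pattern")
  }
  structure(list(dimension = dimension, level = level,
                 variation_type = variation_type,
                 spatial_pattern = spatial_pattern,
                 onset_ms = onset_ms, width_ms = width_ms,
                 amplitude = amplitude,
                 lag_ms = lag_ms, lag_pattern = lag_pattern),
            class = "effect_spec")
}

#' Spatial weight presets over the montage
#'
#' `"occipital"` and `"frontal"` put unit weight on the corresponding
#' 9-electrode preset and zero elsewhere; `"global"` weights all channels
#' equally at 1. Supplying a named numeric vector passes it through after
#' aligning to `channels`.
#'
#' @param preset Preset name or named numeric weight vector.
#' @param channels Montage channel names.
#' @return Numeric weight vector, one entry per channel.
#' @export
spatial_pattern <- function(preset = c("global", "occipital", "frontal"),
                            channels = montage_channels()) {
  if (is.numeric(preset)) {
    if (is.null(names(preset))) {
      stopifnot(length(preset) == length(channels))
      return(as.numeric(preset))
    }
    w <- rep(0, length(channels))
    idx <- match(names(preset), channels)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(names(preset)[is.na(idx)], collapse = ", "))
    w[idx] <- preset
    return(w)
  }
  preset <- match.arg(preset)
  set <- switch(preset,
    global = channels,
    occipital = electrode_preset("peri_occipital", channels),
    frontal = electrode_preset("peri_frontal", channels))
  as.numeric(channels %in% set)
}

hann_bump <- function(t_ms, onset_ms, width_ms) {
  u <- (t_ms - onset_ms) / width_ms
  k <- numeric(length(t_ms))
  inside <- abs(u) < 1
  k[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  k
}

resolve_pattern <- function(p, channels) {
  if (is.character(p)) spatial_pattern(p, channels) else spatial_pattern(p, channels)
}

effect_trial_mask <- function(eff, trials) {
  if (eff$dimension == "category") {
    if (!eff$level %in% trials$category) {
      stop("effect level '", eff$level, "' not present in the design")
    }
    trials$category == eff$level
  } else {
    if (!eff$variation_type %in% trials$variation_type) {
      stop("effect variation_type '", eff$variation_type, "' not in the design")
    }
    if (!eff$level %in% trials$variation_level[trials$variation_type == eff$variation_type]) {
      stop("effect level '", eff$level, "' not present in the design")
    }
    trials$variation_type == eff$variation_type &
      trials$variation_level == eff$level
  }
}

#' Simulate one subject's epoched recording
#'
#' Draws the randomized trial sequence, generates AR(1) noise at the raw
#' sampling rate, adds every matching planted effect, and bins to the 5 ms
#' analysis resolution via [bin_epochs()]. Identical `(cfg, seed,
#' subject_id)` give bit-identical output.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Integer id recorded in the trial table.
#' @param seed Integer seed; the effective RNG stream also folds in
#'   `subject_id` so subjects of one group are independent.
#' @return An `eeg_epochs` object: list with `voltages` (channels x
#'   timebins x trials array, microvolts), `time` (ms, bin centers),
#'   `channels`, `trials` (trial table joined with the design) and
#'   `subject_id`.
#' @export
generate_subject <- function(cfg, subject_id = 1L, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer((as.numeric(seed) * 10007 + subject_id) %% 2147483647))
  trials <- generate_trials(cfg$design, subject_id, cfg$n_reps)
  n_tr <- nrow(trials)
  n_ch <- length(cfg$channel_names)
  dt <- 1000 / cfg$sfreq_raw
  t_raw <- seq(cfg$epoch_window[1], cfg$epoch_window[2], by = dt)
  n_s <- length(t_raw)

  # AR(1) noise, all channels x trials at once; stationary start
  innov <- matrix(stats::rnorm(n_s * n_ch * n_tr, sd = cfg$noise_sd), nrow = n_s)
  if (cfg$ar_coeff > 0) {
    innov[1, ] <- innov[1, ] / sqrt(1 - cfg$ar_coeff^2)
    noise <- stats::filter(innov, cfg$ar_coeff, method = "recursive")
    noise <- matrix(as.numeric(noise), nrow = n_s)
  } else {
    noise <- innov
  }
  raw <- aperm(array(noise, dim = c(n_s, n_ch, n_tr)), c(2, 1, 3))

  if (cfg$shared_noise_sd > 0) {
    ci <- matrix(stats::rnorm(n_s * n_tr, sd = cfg$shared_noise_sd), nrow = n_s)
    if (cfg$ar_coeff > 0) {
      ci[1, ] <- ci[1, ] / sqrt(1 - cfg$ar_coeff^2)
      ci <- matrix(as.numeric(stats::filter(ci, cfg$ar_coeff, method = "recursive")),
                   nrow = n_s)
    }
    for (tr in seq_len(n_tr)) raw[, , tr] <- raw[, , tr] + rep(ci[, tr], each = n_ch)
  }

  for (eff in cfg$effects) {
    mask <- effect_trial_mask(eff, trials)
    if (!any(mask)) next
    pat <- resolve_pattern(eff$spatial_pattern, cfg$channel_names)
    bump <- eff$amplitude * outer(pat, hann_bump(t_raw, eff$onset_ms, eff$width_ms))
    if (!is.null(eff$lag_ms)) {
      lpat <- resolve_pattern(eff$lag_pattern, cfg$channel_names)
      bump <- bump + eff$amplitude *
        outer(lpat, hann_bump(t_raw, eff$onset_ms + eff$lag_ms, eff$width_ms))
    }
    idx <- which(mask)
    raw[, , idx] <- raw[, , idx] + as.vector(bump)
  }

  bin_epochs(raw, sfreq_raw = cfg$sfreq_raw, epoch_window = cfg$epoch_window,
             channel_names = cfg$channel_names, trials = trials,
             subject_id = subject_id)
}

#' Simulate a group of subjects
#'
#' @param cfg A [synth_config()]; `cfg$n_subjects` subjects are drawn.
#' @param seed Base seed; each subject folds its id into the stream.
#' @return List of `eeg_epochs`, one per subject.
#' @export
generate_group <- function(cfg, seed = 1L) {
  lapply(seq_len(cfg$n_subjects), function(s) generate_subject(cfg, s, seed))
}

#' Bin raw epochs to the 5 ms analysis resolution
#'
#' Averages non-overlapping blocks of consecutive raw samples (5 samples at
#' 1 kHz) into 5 ms bins; each output bin carries the time of its first raw
#' sample plus half the block span, i.e. the bin center (+2 ms at 1 kHz).
#' 1005 raw samples spanning -200..+804 ms become 201 bins.
#'
#' @param raw Numeric array, channels x raw_samples x trials.
#' @param sfreq_raw Raw sampling rate (Hz), a multiple of 200.
#' @param epoch_window ms pair giving the time of the first raw sample and
#'   the last.
#' @param channel_names,trials,subject_id Metadata for the returned object.
#' @return An `eeg_epochs` object at 5 ms resolution.
#' @export
bin_epochs <- function(raw, sfreq_raw = 1000, epoch_window = c(-200, 804),
                       channel_names = NULL, trials = NULL, subject_id = NA_integer_) {
  stopifnot(is.array(raw), length(dim(raw)) == 3L)
  d <- dim(raw)
  m <- as.integer(sfreq_raw * 5 / 1000)  # raw samples per 5 ms bin
  if (m < 1L) stop("sfreq_raw below the 5 ms bin resolution")
  if (d[2] %% m != 0L) {
    stop("raw sample count (", d[2], ") is not divisible by the bin size (", m, ")")
  }
  nb <- d[2] %/% m
  dt <- 1000 / sfreq_raw
  if (m == 1L) {
    binned <- raw
  } else {
    # accumulate the m within-bin sample planes; avoids apply() overhead
    tm <- matrix(aperm(raw, c(2, 1, 3)), nrow = d[2])
    acc <- tm[seq(1L, d[2], by = m), , drop = FALSE]
    for (i in 2:m) acc <- acc + tm[seq(i, d[2], by = m), , drop = FALSE]
    binned <- aperm(array(acc / m, dim = c(nb, d[1], d[3])), c(2, 1, 3))
  }
  t_first <- epoch_window[1] + (seq_len(nb) - 1L) * m * dt
  time <- t_first + (m - 1) * dt / 2
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(d[1]))
  dimnames(binned) <- list(channel_names, NULL, NULL)
  structure(list(voltages = binned, time = time, channels = channel_names,
                 trials = trials, subject_id = subject_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$voltages)
  cat("Epoched EEG: ", d[1], " channels x ", d[2], " bins x ", d[3], " trials\n",
      "time ", min(x$time), "..", max(x$time), " ms (bin width ",
      if (d[2] > 1) x$time[2] - x$time[1] else NA, " ms), subject ",
      x$subject_id, "\n", sep = "")
  invisible(x)
}

stopifnot_epochs <- function(x) {
  if (!inherits(x, "eeg_epochs")) stop("expected an eeg_epochs object")
  if (!is.null(x$trials) && nrow(x$trials) != dim(x$voltages)[3]) {
    stop("trial table rows (", nrow(x$trials), ") do not match the trial axis (",
         dim(x$voltages)[3], ")")
  }
  invisible(x)
}
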