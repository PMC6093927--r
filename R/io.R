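#' Write an epoched dataset to a directory
#'
#' On-disk layout: `voltages.f32` (little-endian 32-bit float array,
#' channel-major channels x timebins x trials), `meta.json` (dimensions,
#' channel names, time axis, units) and `trials.tsv` (trial table). The
#' float array round-trips bit-exactly through [read_epochs()].
#'
#' @param epochs An `eeg_epochs` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot_epochs(epochs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "voltages.f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(epochs$voltages), con, size = 4L, endian = "little")
  meta <- list(
    dims = dim(epochs$voltages),
    channel_names = epochs$channels,
    time_ms = epochs$time,
    units = "microvolt",
    subject_id = epochs$subject_id)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- epochs$trials[, c("trial_id", "image_id", "category", "exemplar",
                           "variation_type", "variation_level", "repetition",
                           "subject_id", "presentation_order")]
  utils::write.table(tab, file.path(dir, "trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an epoched dataset written by [write_epochs()]
#'
#' @param dir Directory containing `voltages.f32`, `meta.json`,
#'   `trials.tsv`.
#' @return An `eeg_epochs` object. Shape or metadata inconsistencies (array
#'   size vs dims, trial-table rows vs trial axis, channel count) raise an
#'   error naming the offending field.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L) stop("meta.json field 'dims' must have 3 entries")
  if (length(meta$channel_names) != dims[1]) {
    stop("meta.json field 'channel_names' has ", length(meta$channel_names),
         " entries but dims[1] = ", dims[1],
         "; expected names such as: ", paste(montage_channels()[1:5], collapse = ", "),
         ", ...")
  }
  if (length(meta$time_ms) != dims[2]) {
    stop("meta.json field 'time_ms' does not match dims[2]")
  }
  fn <- file.path(dir, "voltages.f32")
  n <- prod(dims)
  con <- file(fn, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(v) != n) {
    stop("voltages.f32 holds ", length(v), " values but dims imply ", n)
  }
  trials <- utils::read.table(file.path(dir, "trials.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  if (nrow(trials) != dims[3]) {
    stop("trials.tsv has ", nrow(trials), " rows but dims[3] = ", dims[3])
  }
  arr <- array(v, dim = dims, dimnames = list(meta$channel_names, NULL, NULL))
  structure(list(voltages = arr, time = as.numeric(meta$time_ms),
                 channels = meta$channel_names, trials = trials,
                 subject_id = meta$subject_id),
            class = "eeg_epochs")
}

write_curve_tsv <- function(curve, path, sem = NA_real_, n_subjects = 1L) {
  df <- data.frame(time_ms = curve$time, value = curve$values, sem = sem,
                   n_subjects = n_subjects, contrast = curve$contrast,
                   scheme = curve$scheme,
                   electrode_set = paste(curve$electrodes, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates (or reads) a group of epoched datasets, then runs the
#' requested stages in dependency order: pooled and per-condition category
#' decoding with group significance, latency and peak; the selectivity
#' index at the requested times; and the feed-forward/feedback flow
#' between the peri-frontal and peri-occipital presets. All outputs are
#' written as TSV plus one machine-readable JSON summary; reruns with the
#' same config produce byte-identical files.
#'
#' @param cfg A [synth_config()] describing the data (or `data_dirs`, a
#'   character vector of directories to read instead).
#' @param out_dir Output directory.
#' @param analyses Subset of `c("decode", "stats", "selectivity", "flow")`.
#' @param data_dirs Optional pre-written dataset directories.
#' @param seed Integer master seed.
#' @param n_perm Permutations for the flow null.
#' @param selectivity_times_ms Times for the selectivity index.
#' @param alpha Significance level.
#' @return The summary list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(cfg = NULL, out_dir,
                         analyses = c("decode", "stats", "selectivity", "flow"),
                         data_dirs = NULL, seed = 1L, n_perm = 200,
                         selectivity_times_ms = c(150, 300), alpha = 0.05) {
  known <- c("decode", "stats", "selectivity", "flow")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analysis name(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  group <- if (!is.null(data_dirs)) {
    lapply(data_dirs, read_epochs)
  } else {
    generate_group(cfg, seed)
  }
  summary <- list(seed = seed, n_subjects = length(group),
                  alpha = alpha, n_perm = n_perm)

  if (any(c("decode", "stats", "selectivity") %in% analyses)) {
    raw_curves <- lapply(group, function(ep) {
      average_pairs(decode_all_pairs(ep, "category", scheme = "pooled",
                                     baseline = FALSE), "category-average")
    })
    bl_curves <- lapply(raw_curves, function(cv) {
      cv$values <- apply_baseline(cv$values, cv$time)
      cv$baseline_corrected <- TRUE
      cv
    })
    g <- group_curves(bl_curves)
    if ("decode" %in% analyses) {
      gc <- bl_curves[[1]]; gc$values <- g$mean
      write_curve_tsv(gc, file.path(out_dir, "category_pooled_curve.tsv"),
                      sem = g$sem, n_subjects = length(group))
    }
    if ("stats" %in% analyses) {
      trace <- signed_rank_vs_baseline(raw_curves, alpha = alpha)
      utils::write.table(trace, file.path(out_dir, "category_significance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lp <- latency_peak(g$mean, trace, time = g$time)
      summary$category <- lp
    }
  }
  if ("selectivity" %in% analyses) {
    st <- selectivity_trace(group, selectivity_times_ms)
    utils::write.table(st, file.path(out_dir, "selectivity_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$selectivity_index <- stats::setNames(st$mean, paste0("t", st$time_ms))
  }
  if ("flow" %in% analyses) {
    fl <- flow_curves_group(group, function(tr) variation_condition_trials(tr),
                            n_perm = n_perm, seed = seed)
    df <- data.frame(time_ms = fl$time_ms, ff = fl$ff, fb = fl$fb,
                     diff = fl$diff, ff_thresh = fl$ff_thresh,
                     fb_thresh = fl$fb_thresh, sig_ff = fl$sig_ff,
                     sig_fb = fl$sig_fb)
    utils::write.table(df, file.path(out_dir, "flow.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$flow_stages <- flow_stage_boundaries(fl)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# maximal runs of bins where the FF-FB difference is significant with one
# sign: an operational definition of processing-stage boundaries
flow_stage_boundaries <- function(fl) {
  ok <- which(!is.na(fl$sig_diff))
  if (!length(ok)) return(list())
  state <- ifelse(fl$sig_diff[ok] & fl$diff[ok] > 0, "ff",
                  ifelse(fl$sig_diff[ok] & fl$diff[ok] < 0, "fb", "none"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- runs$values != "none"
  lapply(which(keep), function(i) {
    list(direction = runs$values[i],
         start_ms = fl$time_ms[ok[starts[i]]],
         end_ms = fl$time_ms[ok[ends[i]]])
  })
}
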