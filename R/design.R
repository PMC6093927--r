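#' Stimulus categories, variation dimensions and montage
#'
#' The stimulus design crosses 4 object categories x 4 exemplars with 4
#' variation dimensions (size, position, pose, lighting), each manipulated
#' at 3 levels, one variation per image: 192 unique images, i.e. 16 objects
#' each shown under 12 variation conditions.
#'
#' @name design-constants
#' @keywords internal
NULL

CATEGORIES <- c("animal", "car", "face", "plane")
VARIATION_TYPES <- c("size", "position", "pose", "lighting")
N_EXEMPLARS <- 4L
N_LEVELS <- 3L

#' 31-channel analysis montage (10-20 system)
#'
#' Channel names for the 31 analysis electrodes of a 32-channel 10-20
#' montage after excluding the right-mastoid reference. Ordering is
#' front-to-back; the peri-frontal and peri-occipital presets index into
#' this vector.
#'
#' @return Character vector of 31 channel names.
#' @seealso [electrode_preset()]
#' @export
montage_channels <- function() {
  c("FP1", "FPZ", "FP2", "AFZ",
    "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8",
    "T7", "C3", "CZ", "C4", "T8",
    "CP3", "CPZ", "CP4",
    "P7", "P3", "PZ", "P4", "P8",
    "POZ", "O1", "OZ", "O2")
}

#' Electrode-set presets
#'
#' Named electrode subsets used to separate posterior from anterior
#' representational spaces: 9 peri-occipital (P3, P4, P7, P8, PZ, POZ, O1,
#' O2, OZ) and 9 peri-frontal (F3, F4, F7, F8, FZ, AFZ, FP1, FP2, FPZ)
#' channels, or all 31 analysis channels.
#'
#' @param name One of `"all"`, `"peri_occipital"`, `"peri_frontal"`, or a
#'   character vector of channel names (returned as-is after validation).
#' @param channels Full channel vector the preset must be a subset of.
#' @return Character vector of channel names.
#' @export
electrode_preset <- function(name = c("all", "peri_occipital", "peri_frontal"),
                             channels = montage_channels()) {
  if (length(name) > 1L && !identical(name, c("all", "peri_occipital", "peri_frontal"))) {
    chs <- name
  } else {
    name <- match.arg(name)
    chs <- switch(name,
      all = channels,
      peri_occipital = c("P3", "P4", "P7", "P8", "PZ", "POZ", "O1", "O2", "OZ"),
      peri_frontal = c("F3", "F4", "F7", "F8", "FZ", "AFZ", "FP1", "FP2", "FPZ"))
  }
  missing <- setdiff(chs, channels)
  if (length(missing) > 0L) {
    stop("electrode(s) not in montage: ", paste(missing, collapse = ", "),
         "; expected a subset of: ", paste(channels, collapse = ", "))
  }
  chs
}

#' Enumerate the full factorial stimulus design
#'
#' Builds the 192-image design table: 4 categories x 4 exemplars x 4
#' variation dimensions x 3 levels, one variation manipulated per image.
#' Rows are ordered by (category, exemplar, variation_type, level) and
#' `image_id` is the row number under that ordering.
#'
#' @return A data.frame with columns `image_id`, `category`, `exemplar`,
#'   `variation_type`, `variation_level`; exactly 192 distinct rows, each
#'   (category, exemplar) pair appearing 12 times.
#' @examples
#' d <- generate_design()
#' nrow(d)                                  # 192
#' sum(d$variation_type == "size" & d$variation_level == 1)  # 16 objects
#' @export
generate_design <- function() {
  d <- expand.grid(
    variation_level = seq_len(N_LEVELS),
    variation_type = VARIATION_TYPES,
    exemplar = seq_len(N_EXEMPLARS),
    category = CATEGORIES,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("category", "exemplar", "variation_type", "variation_level")]
  d <- d[order(d$category, d$exemplar, d$variation_type, d$variation_level), ]
  rownames(d) <- NULL
  data.frame(image_id = seq_len(nrow(d)), d, stringsAsFactors = FALSE)
}

#' Build a randomized trial table for one subject
#'
#' Each of the 192 images is presented `n_reps` times (default 3) in random
#' order, giving 576 trials per subject at the default design.
#'
#' @param design Design table from [generate_design()].
#' @param subject_id Integer subject identifier.
#' @param n_reps Presentations per image.
#' @return A data.frame of trials joined with the design columns, ordered by
#'   presentation; `presentation_order` is a permutation of `1:nrow`.
#'   Randomness comes from the session RNG; seed it for reproducibility.
#' @export
generate_trials <- function(design, subject_id = 1L, n_reps = 3L) {
  stopifnot(is.data.frame(design), n_reps >= 1L)
  n <- nrow(design) * n_reps
  tab <- design[rep(seq_len(nrow(design)), each = n_reps), ]
  tab$repetition <- rep(seq_len(n_reps), times = nrow(design))
  tab <- data.frame(trial_id = seq_len(n), tab,
                    subject_id = as.integer(subject_id),
                    stringsAsFactors = FALSE)
  # trial_id enumerates the design block-wise (all trials of a category are
  # contiguous in id); presentation_order is the randomized serial position
  tab$presentation_order <- sample.int(n)
  tab <- tab[order(tab$presentation_order), ]
  rownames(tab) <- NULL
  tab
}
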