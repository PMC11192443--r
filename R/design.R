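#' @keywords internal
"_PACKAGE"

# Condition-type labels used throughout.
CT_ML  <- "+M/-L"  # meaningful nonverbal
CT_MPL <- "+M/+L"  # meaningful verbal
CT_NN  <- "-M/-L"  # non-meaningful nonverbal
CONDITION_TYPES <- c(CT_ML, CT_MPL, CT_NN)

LANGUAGE_FROIS <- c("IFGorb", "IFG", "MFG", "AntTemp", "PostTemp")

#' Expected leave-one-out ISC under the additive shared-signal model
#'
#' For series `x_i = sqrt(a) * s + sqrt(1 - a) * e_i` with unit-variance
#' shared signal `s` and independent unit-variance noise `e_i`, the Pearson
#' correlation between one participant and the average of the remaining
#' `n - 1` converges (as the series length grows) to
#' `a / sqrt(a + (1 - a) / (n - 1))`.
#'
#' @param a proportion of variance that is shared, in `[0, 1)`.
#' @param n number of participants (>= 2).
#' @return expected leave-one-out correlation.
#' @export
expected_loo_isc <- function(a, n) {
  stopifnot(all(a >= 0), all(a < 1), all(n >= 2))
  a / sqrt(a + (1 - a) / (n - 1))
}

# The ten naturalistic conditions: type, duration (s, includes the 16 s
# fixations at each end), presentation modality, and number of participants.
paper_conditions <- function() {
  data.frame(
    name = c("AnimShort", "SilentFilm", "IntentShapes", "SoundEffectStory",
             "Story", "AudioPlay", "Dialog", "ExpoText",
             "Flute", "Kaleidoscope"),
    condition_type = c(rep(CT_ML, 4), rep(CT_MPL, 4), rep(CT_NN, 2)),
    duration_s = c(348, 370, 290, 276, 316, 374, 335, 426, 344, 348),
    modality = c("visual", "visual", "visual", "auditory",
                 "auditory", "auditory", "auditory", "auditory",
                 "auditory", "visual"),
    n_participants = c(33, 32, 32, 31, 34, 31, 29, 29, 14, 15),
    stringsAsFactors = FALSE
  )
}

small_conditions <- function() {
  data.frame(
    name = c("MiniFilm", "MiniStory", "MiniMusic"),
    condition_type = c(CT_ML, CT_MPL, CT_NN),
    duration_s = c(120, 120, 120),
    modality = c("visual", "auditory", "auditory"),
    n_participants = c(8, 8, 8),
    stringsAsFactors = FALSE
  )
}

validate_conditions <- function(conditions) {
  stopifnot(is.data.frame(conditions))
  needed <- c("name", "condition_type", "duration_s", "modality", "n_participants")
  missing <- setdiff(needed, names(conditions))
  if (length(missing)) {
    stop("condition table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(conditions$name)) stop("duplicate condition names")
  if (!all(conditions$condition_type %in% CONDITION_TYPES)) {
    stop("condition_type must be one of: ", paste(CONDITION_TYPES, collapse = ", "))
  }
  if (!all(conditions$duration_s > 0)) stop("duration_s must be positive")
  if (!all(conditions$modality %in% c("visual", "auditory"))) {
    stop("modality must be 'visual' or 'auditory'")
  }
  if (!all(conditions$n_participants >= 2)) {
    stop("every condition needs n_participants >= 2 (leave-one-out ISC)")
  }
  invisible(conditions)
}

#' Build a simulation design
#'
#' A design bundles the condition manifest, the shared-signal strength per
#' condition type, per-fROI tracking modifiers, the TR, and a participation
#' matrix saying which participant saw which condition. The `"paper"`
#' template carries the ten naturalistic conditions with their published
#' durations and per-condition Ns; `"small"` is a three-condition miniature
#' (one condition per type) for fast tests.
#'
#' Default tracking strengths were solved from the closed form
#' [expected_loo_isc()] so that, at n = 30 participants, the simulated mean
#' leave-one-out ISCs approximate 0.295 (meaningful verbal), 0.164
#' (meaningful nonverbal) and 0.016 (non-meaningful) -- the condition-type
#' means the analysis is calibrated against.
#'
#' @param template `"paper"` or `"small"`.
#' @param seed integer master seed; drives participant-to-condition
#'   assignment and, downstream, all simulation streams.
#' @param tracking_strength named numeric, proportion of shared variance per
#'   condition type, each in `[0, 1)`.
#' @param froi_modifiers named numeric, multiplicative factor on the shared
#'   variance per fROI; effective proportions must stay in `[0, 1)`.
#' @param tr_s repetition time in seconds.
#' @param n_total_participants size of the participant pool conditions are
#'   sampled from (paper template default 47).
#' @param smooth_fwhm_tr FWHM, in TRs, of the Gaussian temporal smoothing
#'   applied to both signal and noise (mimics hemodynamic autocorrelation).
#' @return an object of class `sim_design`.
#' @export
make_design <- function(template = c("paper", "small"),
                        seed = 1L,
                        tracking_strength = c("+M/+L" = 0.11,
                                              "+M/-L" = 0.047,
                                              "-M/-L" = 0.003),
                        froi_modifiers = NULL,
                        tr_s = 2,
                        n_total_participants = NULL,
                        smooth_fwhm_tr = 3) {
  if (!is.character(template) || !template[1] %in% c("paper", "small")) {
    stop("unknown template: must be \"paper\" or \"small\"")
  }
  template <- template[1]
  conditions <- switch(template,
                       paper = paper_conditions(),
                       small = small_conditions())
  validate_conditions(conditions)
  if (is.null(froi_modifiers)) {
    froi_modifiers <- if (template == "paper") {
      stats::setNames(rep(1, length(LANGUAGE_FROIS)), LANGUAGE_FROIS)
    } else {
      c(IFG = 1, PostTemp = 1)
    }
  }
  if (is.null(n_total_participants)) {
    n_total_participants <- if (template == "paper") 47L else max(conditions$n_participants)
  }
  new_design(conditions, tracking_strength, froi_modifiers, tr_s,
             n_total_participants, smooth_fwhm_tr, seed)
}

#' Build a simulation design from an explicit condition table
#'
#' Like [make_design()] but with a caller-supplied condition manifest, for
#' calibration studies that need arbitrary durations, Ns or condition sets.
#' When the participant pool equals the largest condition N (the default),
#' participation is complete for that condition.
#'
#' @inheritParams make_design
#' @param conditions data.frame with columns `name`, `condition_type`,
#'   `duration_s`, `modality`, `n_participants`.
#' @return a `sim_design`.
#' @export
custom_design <- function(conditions, seed = 1L,
                          tracking_strength = c("+M/+L" = 0.11,
                                                "+M/-L" = 0.047,
                                                "-M/-L" = 0.003),
                          froi_modifiers = c(IFG = 1),
                          tr_s = 2,
                          n_total_participants = max(conditions$n_participants),
                          smooth_fwhm_tr = 3) {
  new_design(conditions, tracking_strength, froi_modifiers, tr_s,
             n_total_participants, smooth_fwhm_tr, seed)
}

new_design <- function(conditions, tracking_strength, froi_modifiers, tr_s,
                       n_total_participants, smooth_fwhm_tr, seed) {
  validate_conditions(conditions)
  stopifnot(tr_s > 0, smooth_fwhm_tr >= 0)
  if (is.null(names(tracking_strength)) ||
      !all(unique(conditions$condition_type) %in% names(tracking_strength))) {
    stop("tracking_strength must be named with every condition type present")
  }
  if (any(tracking_strength < 0) || any(tracking_strength >= 1)) {
    stop("tracking strengths must lie in [0, 1)")
  }
  if (is.null(names(froi_modifiers)) || any(froi_modifiers < 0)) {
    stop("froi_modifiers must be a named non-negative numeric vector")
  }
  a_eff <- outer(tracking_strength[conditions$condition_type], froi_modifiers)
  if (any(a_eff >= 1)) stop("froi_modifiers push an effective shared variance to >= 1")
  if (max(conditions$n_participants) > n_total_participants) {
    stop("participant pool smaller than the largest condition N")
  }

  participants <- sprintf("p%02d", seq_len(n_total_participants))
  participation <- matrix(0L, n_total_participants, nrow(conditions),
                          dimnames = list(participants, conditions$name))
  for (ci in seq_len(nrow(conditions))) {
    set.seed(stream_seed(seed, "participation", conditions$name[ci]))
    chosen <- sample(n_total_participants, conditions$n_participants[ci])
    participation[chosen, ci] <- 1L
  }

  structure(
    list(conditions = conditions,
         tracking_strength = tracking_strength,
         froi_modifiers = froi_modifiers,
         tr_s = tr_s,
         participation = participation,
         smooth_fwhm_tr = smooth_fwhm_tr,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design:", nrow(x$conditions), "conditions,",
      nrow(x$participation), "participants,",
      length(x$froi_modifiers), "fROIs, TR =", x$tr_s, "s\n")
  cat("tracking strengths:",
      paste(sprintf("%s = %g", names(x$tracking_strength), x$tracking_strength),
            collapse = ", "), "\n")
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Serialize a simulation design to JSON
#'
#' @param design a `sim_design`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sim_design"))
  jsonlite::write_json(
    list(conditions = design$conditions,
         tracking_strength = as.list(design$tracking_strength),
         froi_modifiers = as.list(design$froi_modifiers),
         tr_s = design$tr_s,
         smooth_fwhm_tr = design$smooth_fwhm_tr,
         seed = design$seed,
         participation = as.data.frame(design$participation)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
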