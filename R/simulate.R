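# Gaussian temporal smoothing followed by standardization to zero mean,
# unit (n-1) variance. Signal and noise pass through the same kernel, so
# smoothing shapes the autocorrelation without touching the shared-variance
# proportion a.
smooth_standardize <- function(x, fwhm_tr) {
  if (fwhm_tr > 0) {
    sigma <- fwhm_tr / (2 * sqrt(2 * log(2)))
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    n <- length(x)
    # edge-renormalized convolution: weights falling off the series are
    # dropped and the kernel rescaled, avoiding edge attenuation
    num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    x <- as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
  }
  s <- stats::sd(x)
  if (s == 0) stop("degenerate constant series during simulation")
  (x - mean(x)) / s
}

#' Simulate region-level BOLD time courses under the additive model
#'
#' For every participating (participant, condition, fROI) cell the series is
#' `x = sqrt(a) * s + sqrt(1 - a) * e`, where `s` is one shared
#' per-condition signal (the same across participants and fROIs) and `e` is
#' participant- and fROI-specific noise. Both are Gaussian series smoothed
#' with the design's temporal kernel and standardized, so `a` is the
#' proportion of variance locked to the stimulus and the expected
#' leave-one-out ISC follows [expected_loo_isc()]. The effective `a` for a
#' cell is the condition type's tracking strength times the fROI modifier.
#'
#' Output is deterministic given the design (every random stream is seeded
#' via [stream_seed()] from `design$seed`).
#'
#' @param design a `sim_design` from [make_design()].
#' @return a raw (unpreprocessed) `timecourse_set`.
#' @export
simulate_timecourses <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  conds <- design$conditions
  frois <- names(design$froi_modifiers)
  series <- list()
  for (ci in seq_len(nrow(conds))) {
    cond <- conds$name[ci]
    n_t <- round(conds$duration_s[ci] / design$tr_s)
    parts <- rownames(design$participation)[design$participation[, cond] == 1L]
    set.seed(stream_seed(design$seed, "signal", cond))
    s <- smooth_standardize(stats::rnorm(n_t), design$smooth_fwhm_tr)
    a_type <- design$tracking_strength[[conds$condition_type[ci]]]
    series[[cond]] <- list()
    for (froi in frois) {
      a <- a_type * design$froi_modifiers[[froi]]
      m <- matrix(NA_real_, n_t, length(parts), dimnames = list(NULL, parts))
      for (p in parts) {
        set.seed(stream_seed(design$seed, "noise", cond, froi, p))
        e <- smooth_standardize(stats::rnorm(n_t), design$smooth_fwhm_tr)
        m[, p] <- sqrt(a) * s + sqrt(1 - a) * e
      }
      series[[cond]][[froi]] <- m
    }
  }
  condition_types <- stats::setNames(conds$condition_type, conds$name)
  timecourse_set(series, design$tr_s, condition_types)
}

#' Simulate a resting-state scan
#'
#' Pure-noise series (shared variance 0) labelled condition `"rest"`, used
#' as the negative control: leave-one-out ISCs on rest should not exceed
#' zero. Defaults mirror a 5-minute rest scan in 10 participants.
#'
#' @param n_participants number of resting participants (>= 2).
#' @param duration_s scan duration in seconds.
#' @param design a `sim_design` supplying TR, fROIs, smoothing and the seed.
#' @return a raw `timecourse_set` with the single condition `"rest"`.
#' @export
simulate_rest <- function(n_participants = 10, duration_s = 300, design) {
  stopifnot(inherits(design, "sim_design"))
  if (n_participants < 2) stop("n_participants must be >= 2 (leave-one-out ISC)")
  n_t <- round(duration_s / design$tr_s)
  parts <- sprintf("r%02d", seq_len(n_participants))
  frois <- names(design$froi_modifiers)
  mats <- lapply(frois, function(froi) {
    m <- matrix(NA_real_, n_t, n_participants, dimnames = list(NULL, parts))
    for (p in parts) {
      set.seed(stream_seed(design$seed, "rest", froi, p))
      m[, p] <- smooth_standardize(stats::rnorm(n_t), design$smooth_fwhm_tr)
    }
    m
  })
  names(mats) <- frois
  timecourse_set(list(rest = mats), design$tr_s, c(rest = "rest"))
}

#' Simulate time courses whose shared signal is concentrated in bursts
#'
#' Constructive fixture for the peak-removal analysis: the shared signal is
#' near-zero baseline noise punctuated by brief high-amplitude bursts, so
#' nearly all stimulus-locked variance sits in the positive excursions of
#' the group-average series (the detected peaks). Removing peak time points
#' should therefore collapse the ISC, while removing troughs should not.
#'
#' @param n_participants participants (>= 2).
#' @param n_timepoints series length in samples.
#' @param n_bursts number of bursts planted in the shared signal.
#' @param burst_len samples per burst.
#' @param burst_height burst amplitude relative to the baseline sd (1).
#' @param a proportion of variance shared (as in [simulate_timecourses()]).
#' @param frois fROI names.
#' @param tr_s repetition time (s).
#' @param seed integer seed.
#' @return a raw `timecourse_set` with one condition `"bursty"` of
#'   condition type `"+M/-L"`, plus attribute `"burst_indices"` (pre-trim).
#' @export
simulate_bursts <- function(n_participants = 20, n_timepoints = 200,
                            n_bursts = 10, burst_len = 2, burst_height = 6,
                            a = 0.3, frois = c("IFG", "PostTemp"),
                            tr_s = 2, seed = 1L) {
  stopifnot(n_participants >= 2, a >= 0, a < 1,
            n_bursts * burst_len < n_timepoints / 2)
  set.seed(stream_seed(seed, "burst-signal"))
  s <- stats::rnorm(n_timepoints, sd = 0.3)
  # burst onsets spaced so bursts never collide; avoid the onset-trim window
  starts <- sort(sample(seq(8, n_timepoints - burst_len, by = burst_len + 4),
                        n_bursts))
  burst_idx <- unique(as.vector(outer(seq_len(burst_len) - 1L, starts, "+")))
  s[burst_idx] <- s[burst_idx] + burst_height
  s <- (s - mean(s)) / stats::sd(s)
  parts <- sprintf("p%02d", seq_len(n_participants))
  mats <- lapply(frois, function(froi) {
    m <- matrix(NA_real_, n_timepoints, n_participants,
                dimnames = list(NULL, parts))
    for (p in parts) {
      set.seed(stream_seed(seed, "burst-noise", froi, p))
      e <- stats::rnorm(n_timepoints)
      e <- (e - mean(e)) / stats::sd(e)
      m[, p] <- sqrt(a) * s + sqrt(1 - a) * e
    }
    m
  })
  names(mats) <- frois
  out <- timecourse_set(list(bursty = mats), tr_s, c(bursty = "+M/-L"))
  attr(out, "burst_indices") <- sort(burst_idx)
  out
}
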