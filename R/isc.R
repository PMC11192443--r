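#' Preprocess a timecourse_set for ISC analysis
#'
#' Drops the first `round(onset_exclusion_s / tr_s)` samples of every series
#' (6 s = 3 samples at TR 2 s, excluding the initial hemodynamic rise) and
#' temporally z-scores each remaining series (mean 0, unit n-1 sd).
#'
#' @param tcs a raw `timecourse_set`.
#' @param onset_exclusion_s override the set's onset exclusion (seconds).
#' @return a preprocessed `timecourse_set`.
#' @export
preprocess_timecourses <- function(tcs, onset_exclusion_s = tcs$onset_exclusion_s) {
  stopifnot(inherits(tcs, "timecourse_set"), onset_exclusion_s >= 0)
  n_drop <- round(onset_exclusion_s / tcs$tr_s)
  series <- tcs$series
  for (cond in names(series)) {
    for (froi in names(series[[cond]])) {
      m <- series[[cond]][[froi]]
      if (nrow(m) <= n_drop + 2) {
        stop("series too short for onset exclusion in ", cond, " / ", froi)
      }
      if (n_drop > 0) m <- m[-seq_len(n_drop), , drop = FALSE]
      sds <- apply(m, 2, stats::sd)
      if (any(sds == 0)) {
        bad <- colnames(m)[sds == 0][1]
        stop("constant series after trimming: participant ", bad,
             ", condition ", cond, ", fROI ", froi)
      }
      series[[cond]][[froi]] <- sweep(sweep(m, 2, colMeans(m)), 2, sds, `/`)
    }
  }
  timecourse_set(series, tcs$tr_s, tcs$condition_types,
                 onset_exclusion_s = onset_exclusion_s, preprocessed = TRUE)
}

#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`. Correlations of exactly +/-1 are an error by default
#' (downstream mixed models cannot absorb infinities); pass `clip = TRUE`
#' to clamp them at `1 - 1e-7` first.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param clip clamp `|r| = 1` to `1 - 1e-7` instead of erroring.
#' @return Fisher-transformed value(s).
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("correlations must be finite and within [-1, 1]")
  }
  if (any(abs(r) == 1)) {
    if (!clip) stop("|r| = 1 has infinite Fisher z; use clip = TRUE to clamp")
    r <- sign(r) * pmin(abs(r), 1 - 1e-7)
  }
  atanh(r)
}

# Leave-one-out correlations for one time x participant matrix of z-scored
# series: r_i = cor(x_i, mean over j != i of x_j). The loop-free form uses
# the row-sum identity mean_{j != i} x_j = (rowSums(X) - x_i) / (n - 1);
# the brute-force oracle in the tests recomputes this with explicit loops.
loo_cor_matrix <- function(m) {
  n <- ncol(m)
  if (n < 2) stop("leave-one-out ISC needs >= 2 participants")
  tot <- rowSums(m)
  r <- numeric(n)
  for (i in seq_len(n)) {
    avg <- (tot - m[, i]) / (n - 1)
    if (stats::sd(avg) == 0) {
      stop("zero-variance leave-one-out average for participant ",
           colnames(m)[i])
    }
    r[i] <- stats::cor(m[, i], avg)
  }
  stats::setNames(r, colnames(m))
}

#' Leave-one-out intersubject correlations for one condition and fROI
#'
#' For each participant, the Pearson correlation between their z-scored
#' series and the average of the remaining participants' z-scored series.
#' The leave-one-out average is not re-z-scored (correlation is invariant
#' to its scale).
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param condition condition name.
#' @param froi fROI name.
#' @return data.frame with columns `participant`, `r`.
#' @export
loo_isc <- function(tcs, condition, froi) {
  stopifnot(inherits(tcs, "timecourse_set"))
  if (!tcs$preprocessed) {
    stop("time courses must be preprocessed (see preprocess_timecourses)")
  }
  if (!condition %in% names(tcs$series)) stop("unknown condition: ", condition)
  if (!froi %in% names(tcs$series[[condition]])) stop("unknown fROI: ", froi)
  m <- tcs$series[[condition]][[froi]]
  r <- loo_cor_matrix(m)
  data.frame(participant = names(r), r = unname(r), stringsAsFactors = FALSE)
}

#' Compute the full ISC table
#'
#' Applies [loo_isc()] and [fisher_z()] to every (condition, fROI) cell of
#' a preprocessed `timecourse_set`. The resulting long table — one row per
#' participating (participant, condition, fROI) — is the unit of all
#' downstream statistics.
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param clip passed to [fisher_z()].
#' @return a data.frame of class `isc_table` with columns `participant`,
#'   `condition`, `condition_type`, `froi`, `r`, `z`, `n_timepoints`.
#' @export
compute_isc_table <- function(tcs, clip = FALSE) {
  stopifnot(inherits(tcs, "timecourse_set"))
  rows <- list()
  for (cond in names(tcs$series)) {
    for (froi in names(tcs$series[[cond]])) {
      res <- loo_isc(tcs, cond, froi)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = res$participant,
        condition = cond,
        condition_type = tcs$condition_types[[cond]],
        froi = froi,
        r = res$r,
        z = fisher_z(res$r, clip = clip),
        n_timepoints = nrow(tcs$series[[cond]][[froi]]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("isc_table", "data.frame")
  out
}

#' Resting-state baseline check
#'
#' Averages Fisher z across fROIs within each participant and tests whether
#' the participant means exceed zero with a one-sample, one-tailed t test
#' (H1: mean > 0, df = n - 1). A healthy pipeline shows no positive rest
#' ISC: the test should be non-significant at the nominal rate.
#'
#' @param isc an `isc_table` restricted to the rest condition (any table
#'   with a single condition works).
#' @return list with `t`, `df`, `p`, and `participant_means`.
#' @export
rest_baseline_test <- function(isc) {
  stopifnot(is.data.frame(isc), all(c("participant", "z") %in% names(isc)))
  means <- tapply(isc$z, isc$participant, mean)
  n <- length(means)
  if (n < 2) stop("rest baseline test needs >= 2 participants")
  if (stats::sd(means) == 0) {
    # degenerate all-equal means: t is 0/0 for mean 0; report t = 0, p = 0.5
    if (mean(means) != 0) stop("constant nonzero participant means; t undefined")
    return(list(t = 0, df = n - 1, p = 0.5, participant_means = means))
  }
  tt <- stats::t.test(as.numeric(means), mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, participant_means = means)
}

#' Write / read an ISC table as TSV
#' @param isc an `isc_table`.
#' @param path file path.
#' @return `path` (write) or an `isc_table` (read).
#' @export
write_isc_table <- function(isc, path) {
  utils::write.table(isc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isc_table
#' @export
read_isc_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("isc_table", "data.frame")
  out
}
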