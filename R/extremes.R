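#' Detect peak or trough time points of a condition's group-average series
#'
#' The group series is the mean of the (preprocessed) series over all
#' participating participants and all fROIs, z-normalized. Peaks are the
#' time points strictly above `+threshold`; troughs strictly below
#' `-threshold`. Indices are 1-based positions in the post-trim series.
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param condition condition name.
#' @param polarity `"peak"` or `"trough"`.
#' @param threshold z-unit threshold (default 1).
#' @param per_froi if TRUE, detect on each fROI's own participant-average
#'   series instead of the grand average (off by default; the standard
#'   procedure pools fROIs).
#' @return an object of class `extreme_point_set` (or a named list of them
#'   when `per_froi = TRUE`): `condition`, `polarity`, `indices` (sorted),
#'   `threshold`, `group_series`.
#' @export
detect_extremes <- function(tcs, condition, polarity = c("peak", "trough"),
                            threshold = 1, per_froi = FALSE) {
  stopifnot(inherits(tcs, "timecourse_set"))
  polarity <- match.arg(polarity)
  if (!tcs$preprocessed) stop("detect_extremes expects preprocessed series")
  if (!condition %in% names(tcs$series)) stop("unknown condition: ", condition)
  mats <- tcs$series[[condition]]
  detect_one <- function(avg) {
    s <- stats::sd(avg)
    if (s == 0) stop("constant group-average series; cannot z-normalize")
    gz <- (avg - mean(avg)) / s
    idx <- if (polarity == "peak") which(gz > threshold) else which(gz < -threshold)
    structure(list(condition = condition, polarity = polarity,
                   indices = sort(idx), threshold = threshold,
                   group_series = gz),
              class = "extreme_point_set")
  }
  if (per_froi) {
    lapply(mats, function(m) detect_one(rowMeans(m)))
  } else {
    grand <- rowMeans(do.call(cbind, unname(mats)))
    detect_one(grand)
  }
}

#' @export
print.extreme_point_set <- function(x, ...) {
  cat(sprintf("%s points for '%s' (|z| > %g): %d indices\n",
              x$polarity, x$condition, x$threshold, length(x$indices)))
  invisible(x)
}

# Mean Fisher z across participants and fROIs for one condition after
# keeping only the rows in `keep`. Fully vectorized column-wise Pearson of
# each participant against their leave-one-out average.
mean_z_after_keep <- function(mats, keep) {
  zs <- lapply(mats, function(m) {
    a <- m[keep, , drop = FALSE]
    n <- ncol(a)
    loo <- (rowSums(a) - a) / (n - 1)
    ac <- sweep(a, 2, colMeans(a))
    mc <- sweep(loo, 2, colMeans(loo))
    denom <- sqrt(colSums(ac^2) * colSums(mc^2))
    if (any(denom == 0)) stop("zero-variance series after removal")
    r <- colSums(ac * mc) / denom
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  })
  mean(unlist(zs))
}

#' Recompute ISCs after deleting specified time points
#'
#' The listed time points are removed from every participant's series for
#' the condition (the same deletion in every fROI); leave-one-out ISC and
#' the Fisher transform are then applied to the concatenated remainder.
#' Deleted points are dropped, not interpolated.
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param condition condition name.
#' @param indices time-point indices to delete (post-trim, 1-based). Empty
#'   is allowed and reproduces the plain ISC table for the condition.
#' @return an `isc_table` restricted to `condition`.
#' @export
removed_isc <- function(tcs, condition, indices) {
  stopifnot(inherits(tcs, "timecourse_set"))
  if (!tcs$preprocessed) stop("removed_isc expects preprocessed series")
  if (!condition %in% names(tcs$series)) stop("unknown condition: ", condition)
  mats <- tcs$series[[condition]]
  n_t <- nrow(mats[[1]])
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && (min(indices) < 1 || max(indices) > n_t)) {
    stop("removal indices outside 1..", n_t)
  }
  if (n_t - length(indices) < 3) {
    stop("removal would leave fewer than 3 time points")
  }
  keep <- setdiff(seq_len(n_t), indices)
  sub <- timecourse_set(
    stats::setNames(list(lapply(mats, function(m) m[keep, , drop = FALSE])),
                    condition),
    tcs$tr_s, tcs$condition_types[condition],
    onset_exclusion_s = tcs$onset_exclusion_s, preprocessed = TRUE)
  compute_isc_table(sub)
}

#' Random time-point-removal null distribution
#'
#' Each of `n_iter` draws removes `m` distinct time points chosen uniformly
#' at random and records the mean Fisher z across participants and fROIs
#' for the condition. Peak- or trough-removed means are then referred to
#' this null with a one-tailed (lower) add-one empirical p value: removal
#' of genuinely informative points should fall in the null's lower tail.
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param condition condition name.
#' @param m number of time points removed per draw (matched to the
#'   condition's peak count in the standard analysis).
#' @param n_iter number of draws (default 10000).
#' @param seed integer seed (own counter-based stream per condition).
#' @return an object of class `null_distribution`: `condition`,
#'   `m_removed`, `n_iter`, `values`, `seed`.
#' @export
random_removal_null <- function(tcs, condition, m, n_iter = 10000, seed = 1L) {
  stopifnot(inherits(tcs, "timecourse_set"), n_iter >= 1)
  if (!tcs$preprocessed) stop("random_removal_null expects preprocessed series")
  if (!condition %in% names(tcs$series)) stop("unknown condition: ", condition)
  mats <- tcs$series[[condition]]
  n_t <- nrow(mats[[1]])
  if (m < 0 || m >= n_t - 3) stop("m must satisfy 0 <= m < length - 3")
  set.seed(stream_seed(seed, "removal-null", condition))
  values <- vapply(seq_len(n_iter), function(i) {
    drop <- if (m > 0) sample.int(n_t, m) else integer(0)
    mean_z_after_keep(mats, setdiff(seq_len(n_t), drop))
  }, numeric(1))
  structure(list(condition = condition, m_removed = as.integer(m),
                 n_iter = as.integer(n_iter), values = values,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.025, 0.5, 0.975))
  cat(sprintf("removal null for '%s': m = %d, %d draws; median %.4f [%.4f, %.4f]\n",
              x$condition, x$m_removed, x$n_iter, q[2], q[1], q[3]))
  invisible(x)
}

#' Empirical p value of an observed mean ISC against a removal null
#'
#' One-tailed lower with add-one smoothing:
#' `p = (1 + #\{null <= observed\}) / (1 + n_iter)`.
#'
#' @param null a `null_distribution`.
#' @param observed observed mean Fisher z (e.g. mean of a peak-removed
#'   `isc_table`'s `z` column).
#' @return empirical p value.
#' @export
null_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "null_distribution"), is.finite(observed))
  (1 + sum(null$values <= observed)) / (1 + null$n_iter)
}

#' Two-sample test of peak-removed vs trough-removed ISCs
#'
#' Pools Fisher z over participants and fROIs in each table and applies a
#' two-sample pooled-variance t test (two-tailed); with g observations per
#' group the df is `2 g - 2`. The caller is responsible for matching the
#' trough removal count to the peak count (see [peak_trough_analysis()]).
#'
#' @param peak_isc,trough_isc `isc_table`s for the same condition.
#' @return list with `t`, `df`, `p`, and the two group means.
#' @export
peak_vs_trough_test <- function(peak_isc, trough_isc) {
  zp <- peak_isc$z
  zt <- trough_isc$z
  if (length(zp) < 2 || length(zt) < 2) stop("each group needs >= 2 values")
  tt <- stats::t.test(zp, zt, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_peak_removed = mean(zp), mean_trough_removed = mean(zt))
}

#' Full peak/trough-removal analysis for a set of conditions
#'
#' For each condition: detect peaks and troughs (|z| > `threshold` on the
#' participant- and fROI-averaged series), recompute ISCs with peaks
#' removed and with the `m` lowest-valued trough points removed (`m` = peak
#' count, the head-to-head adjustment), build the `m`-matched random
#' removal null, and test (a) each removal against the null (one-tailed
#' empirical p) and (b) peak- vs trough-removed directly (two-sample t).
#' Across-condition p values are FDR-adjusted (Benjamini-Hochberg).
#'
#' @param tcs a preprocessed `timecourse_set`.
#' @param conditions conditions to analyse (default: all in `tcs`).
#' @param threshold peak/trough z threshold (default 1).
#' @param n_iter null draws per condition (default 10000).
#' @param seed integer seed.
#' @return data.frame, one row per condition: peak/trough counts, observed
#'   means, empirical p values, t statistics, and FDR-adjusted p values.
#' @export
peak_trough_analysis <- function(tcs, conditions = tcs_conditions(tcs),
                                 threshold = 1, n_iter = 10000, seed = 1L) {
  rows <- lapply(conditions, function(cond) {
    peaks <- detect_extremes(tcs, cond, "peak", threshold)
    troughs <- detect_extremes(tcs, cond, "trough", threshold)
    m <- length(peaks$indices)
    if (m == 0) {
      warning("no peak time points for '", cond, "'; condition skipped")
      return(NULL)
    }
    # head-to-head adjustment: the m most extreme trough points
    tr_idx <- troughs$indices[order(peaks$group_series[troughs$indices])]
    tr_idx <- sort(utils::head(tr_idx, m))
    peak_tab <- removed_isc(tcs, cond, peaks$indices)
    trough_tab <- removed_isc(tcs, cond, tr_idx)
    null <- random_removal_null(tcs, cond, m, n_iter = n_iter, seed = seed)
    ht <- peak_vs_trough_test(peak_tab, trough_tab)
    full_tab <- removed_isc(tcs, cond, integer(0))
    data.frame(
      condition = cond,
      n_peaks = m,
      n_troughs_all = length(troughs$indices),
      mean_z = mean(full_tab$z),
      mean_z_peak_removed = mean(peak_tab$z),
      mean_z_trough_removed = mean(trough_tab$z),
      p_peak_vs_null = null_pvalue(null, mean(peak_tab$z)),
      p_trough_vs_null = null_pvalue(null, mean(trough_tab$z)),
      t_peak_vs_trough = ht$t,
      df_peak_vs_trough = ht$df,
      p_peak_vs_trough = ht$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(out)
  out$p_fdr_peak_vs_null <- fdr_bh(out$p_peak_vs_null)
  out$p_fdr_trough_vs_null <- fdr_bh(out$p_trough_vs_null)
  out$p_fdr_peak_vs_trough <- fdr_bh(out$p_peak_vs_trough)
  rownames(out) <- NULL
  out
}

#' Write an extreme_point_set or null_distribution as JSON
#' @param x an `extreme_point_set` or `null_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extremes_json <- function(x, path) {
  stopifnot(inherits(x, "extreme_point_set") || inherits(x, "null_distribution"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
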