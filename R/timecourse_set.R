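#' Construct a set of region-level BOLD time courses
#'
#' The central container of the pipeline: for every condition, a named list
#' of `time x participant` matrices, one per fROI. Column names are
#' participant identifiers; within a condition all series share one length.
#'
#' @param series named list: condition -> (named list: froi -> matrix with
#'   one column per participating participant).
#' @param tr_s repetition time in seconds.
#' @param condition_types named character vector mapping each condition to
#'   its condition type.
#' @param onset_exclusion_s seconds dropped from the series start during
#'   [preprocess_timecourses()] (default 6).
#' @param preprocessed logical; whether trimming + z-scoring has been applied.
#' @return an object of class `timecourse_set`.
#' @export
timecourse_set <- function(series, tr_s, condition_types,
                           onset_exclusion_s = 6, preprocessed = FALSE) {
  stopifnot(is.list(series), length(series) > 0, tr_s > 0,
            onset_exclusion_s >= 0)
  conds <- names(series)
  if (is.null(conds) || any(!nzchar(conds))) stop("series must be named by condition")
  if (!all(conds %in% names(condition_types))) {
    stop("condition_types must cover every condition in `series`")
  }
  for (cond in conds) {
    frois <- series[[cond]]
    if (!is.list(frois) || is.null(names(frois))) {
      stop("series[['", cond, "']] must be a named list of fROI matrices")
    }
    lens <- vapply(frois, nrow, integer(1))
    if (length(unique(lens)) != 1) {
      stop("unequal series lengths across fROIs within condition '", cond, "'")
    }
    for (froi in names(frois)) {
      m <- frois[[froi]]
      if (!is.matrix(m) || is.null(colnames(m))) {
        stop("each fROI entry must be a matrix with participant column names (",
             cond, " / ", froi, ")")
      }
    }
  }
  structure(list(series = series, tr_s = tr_s,
                 condition_types = condition_types,
                 onset_exclusion_s = onset_exclusion_s,
                 preprocessed = preprocessed),
            class = "timecourse_set")
}

#' @export
print.timecourse_set <- function(x, ...) {
  conds <- names(x$series)
  cat("timecourse_set:", length(conds), "condition(s), TR =", x$tr_s, "s,",
      if (x$preprocessed) "preprocessed" else "raw", "\n")
  for (cond in conds) {
    frois <- x$series[[cond]]
    cat(sprintf("  %-18s [%s] %d fROIs x %d participants x %d samples\n",
                cond, x$condition_types[[cond]], length(frois),
                ncol(frois[[1]]), nrow(frois[[1]])))
  }
  invisible(x)
}

#' Conditions / fROIs / participants present in a timecourse_set
#' @param tcs a `timecourse_set`.
#' @return character vector.
#' @export
tcs_conditions <- function(tcs) names(tcs$series)

#' @rdname tcs_conditions
#' @param condition condition name.
#' @export
tcs_frois <- function(tcs, condition = tcs_conditions(tcs)[1]) {
  names(tcs$series[[condition]])
}

#' @rdname tcs_conditions
#' @export
tcs_participants <- function(tcs, condition = tcs_conditions(tcs)[1]) {
  colnames(tcs$series[[condition]][[1]])
}

#' Flatten a timecourse_set to a tidy data.frame
#'
#' One row per (participant, condition, froi, t_index) with the BOLD value;
#' the on-disk TSV format.
#'
#' @param x a `timecourse_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns participant, condition, froi, t_index, bold.
#' @export
as.data.frame.timecourse_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- vector("list", 0L)
  for (cond in names(x$series)) {
    for (froi in names(x$series[[cond]])) {
      m <- x$series[[cond]][[froi]]
      out[[length(out) + 1L]] <- data.frame(
        participant = rep(colnames(m), each = nrow(m)),
        condition = cond,
        froi = froi,
        t_index = rep(seq_len(nrow(m)), times = ncol(m)),
        bold = as.vector(m),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write / read a timecourse_set as tidy TSV
#'
#' The TSV holds the flattened series; condition types, TR and the onset
#' exclusion are carried in `#`-prefixed header comments so a round trip
#' reconstructs the object exactly.
#'
#' @param tcs a `timecourse_set`.
#' @param path file path.
#' @return `path` (write) or a `timecourse_set` (read).
#' @export
write_timecourses <- function(tcs, path) {
  stopifnot(inherits(tcs, "timecourse_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s=%s", format(tcs$tr_s, digits = 17)), con)
  writeLines(sprintf("# onset_exclusion_s=%s",
                     format(tcs$onset_exclusion_s, digits = 17)), con)
  writeLines(sprintf("# preprocessed=%d", as.integer(tcs$preprocessed)), con)
  writeLines(sprintf("# condition_type %s=%s",
                     names(tcs$condition_types), tcs$condition_types), con)
  df <- as.data.frame(tcs)
  df$bold <- format(df$bold, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get1 <- function(key) {
    v <- sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    if (!length(v)) stop("missing header field: ", key)
    v
  }
  tr_s <- as.numeric(get1("tr_s"))
  onset <- as.numeric(get1("onset_exclusion_s"))
  prep <- as.integer(get1("preprocessed")) == 1L
  ct_lines <- hdr[grepl("^# condition_type ", hdr)]
  ct_kv <- sub("^# condition_type ", "", ct_lines)
  condition_types <- stats::setNames(sub("^[^=]*=", "", ct_kv),
                                     sub("=.*$", "", ct_kv))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  series <- list()
  for (cond in unique(df$condition)) {
    dfc <- df[df$condition == cond, ]
    series[[cond]] <- list()
    for (froi in unique(dfc$froi)) {
      dff <- dfc[dfc$froi == froi, ]
      parts <- unique(dff$participant)
      tmax <- max(dff$t_index)
      m <- matrix(NA_real_, tmax, length(parts),
                  dimnames = list(NULL, parts))
      m[cbind(dff$t_index, match(dff$participant, parts))] <- dff$bold
      series[[cond]][[froi]] <- m
    }
  }
  timecourse_set(series, tr_s, condition_types,
                 onset_exclusion_s = onset, preprocessed = prep)
}
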