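# Reading, validation and regularization of raw feature-value recordings.
#
# A recording arrives as a wide CSV (one timestamp column, one column per
# facial feature). Internally it is held in long form (`raw_recording`) until
# it has been resampled onto a uniform grid (`feature_series`), because raw
# observations may be irregular (frames every ~3 s) and may contain holes.

#' Construct a raw recording from long-form observations
#'
#' A raw recording is the pre-regularization container: one row per
#' (timestamp, feature) observation, possibly irregular and with missing
#' values. Timestamps are seconds from the start of the recording.
#'
#' @param records Data frame with columns `t` (seconds, non-negative,
#'   non-decreasing within each feature), `feature` (label) and `value`
#'   (numeric, `NA` for missing).
#' @return An object of class `raw_recording` with elements `records` and
#'   `features` (labels in first-appearance order, which is preserved all the
#'   way to the regularized matrix).
#' @seealso [read_feature_csv()], [regularize()]
#' @export
raw_recording <- function(records) {
  if (!is.data.frame(records) || !all(c("t", "feature", "value") %in% names(records)))
    stop_input("records must be a data frame with columns t, feature, value")
  if (nrow(records) == 0L)
    stop_input("recording contains no observations")
  records$t <- as.numeric(records$t)
  records$feature <- as.character(records$feature)
  records$value <- as.numeric(records$value)
  if (anyNA(records$t) || any(records$t < 0))
    stop_input("timestamps must be non-negative seconds from start")
  features <- unique(records$feature)
  # stable sort by time keeps the per-feature order intact
  records <- records[order(records$t), , drop = FALSE]
  rownames(records) <- NULL
  for (f in features) {
    v <- records$value[records$feature == f]
    if (!any(!is.na(v)))
      stop_input("feature '%s' has no non-missing values", f)
  }
  structure(list(records = records, features = features),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d observations, %d feature(s): %s\n",
              nrow(x$records), length(x$features),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

parse_timestamps <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- as.character(v)
  num <- suppressWarnings(as.numeric(v))
  nonblank <- !is.na(v) & nzchar(trimws(v))
  if (any(!is.na(num[nonblank]))) return(num)
  # fall back to ISO date-times, reported as seconds from the first stamp
  tt <- tryCatch(
    suppressWarnings(as.POSIXct(v, tz = "UTC",
      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%H:%M:%OS"))),
    error = function(e) rep(as.POSIXct(NA), length(v)))
  if (all(is.na(tt))) return(rep(NA_real_, length(v)))
  as.numeric(tt) - min(as.numeric(tt), na.rm = TRUE)
}

#' Read a wide-format feature-value CSV
#'
#' Expects a header row, a timestamp column (seconds from start, or an ISO
#' date-time which is converted to seconds from the first stamp) and one
#' column per feature. Cells that do not parse as numbers become missing
#' values and are filled later by [regularize()].
#'
#' @param path Path to the CSV file.
#' @param column_spec Optional named character vector mapping CSV column
#'   names to feature labels (`c(csv_col = "label", ...)`); its order fixes
#'   the feature order. `NULL` keeps every non-timestamp column under its own
#'   name.
#' @param time_col Name of the timestamp column (default `"t"`).
#' @return A [raw_recording()].
#' @export
read_feature_csv <- function(path, column_spec = NULL, time_col = "t") {
  if (!file.exists(path)) stop_input("file not found: '%s'", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!time_col %in% names(df))
    stop_input("timestamp column '%s' not found in '%s' (missing header row?)",
               time_col, path)
  if (is.null(column_spec)) {
    cols <- setdiff(names(df), time_col)
    if (length(cols) == 0L) stop_input("no feature columns in '%s'", path)
    column_spec <- stats::setNames(cols, cols)
  }
  absent <- setdiff(names(column_spec), names(df))
  if (length(absent))
    stop_input("feature column(s) not in file: %s", paste(absent, collapse = ", "))
  t <- parse_timestamps(df[[time_col]])
  keep <- !is.na(t)
  if (!any(keep)) stop_input("no rows with a parseable timestamp in '%s'", path)
  df <- df[keep, , drop = FALSE]
  t <- t[keep]
  recs <- do.call(rbind, lapply(seq_along(column_spec), function(i) {
    col <- names(column_spec)[i]
    data.frame(t = t,
               feature = unname(column_spec[i]),
               value = suppressWarnings(as.numeric(as.character(df[[col]]))),
               stringsAsFactors = FALSE)
  }))
  raw_recording(recs)
}

#' Construct a uniformly sampled feature series
#'
#' @param values Numeric matrix (time rows x feature columns) with column
#'   names; no missing entries.
#' @param start_time First sample time in seconds.
#' @param step Sampling interval in seconds.
#' @return Object of class `feature_series` with elements `start_time`,
#'   `step`, `names`, `values` and `n`.
#' @export
feature_series <- function(values, start_time = 0, step = 1) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop_config("feature matrix must have column names")
  if (!is.numeric(values) || anyNA(values))
    stop_input("feature series must be numeric with no missing entries")
  if (step <= 0) stop_config("step must be positive")
  structure(list(start_time = as.numeric(start_time), step = as.numeric(step),
                 names = colnames(values), values = values, n = nrow(values)),
            class = "feature_series")
}

#' Sample times of a feature series
#' @param series A [feature_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  series$start_time + (seq_len(series$n) - 1) * series$step
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> n=%d, step=%gs, start=%gs, features: %s\n",
              x$n, x$step, x$start_time, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.feature_series <- function(x, ...) {
  data.frame(t = series_times(x), x$values, check.names = FALSE)
}

# Forward fill with the first observation back-filled over any leading gap.
forward_fill <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop_input("cannot fill an all-missing column")
  idx <- cumsum(!is.na(x))
  x[obs][pmax(idx, 1L)]
}

#' Resample a raw recording onto a uniform grid
#'
#' Places observations on the grid `first_t + k * step`; each grid cell takes
#' the most recent observation at or before it (forward fill, matching the
#' convention of padding ~3 s frame intervals out to 1 Hz with the previous
#' value). Grid cells before a feature's first observation are back-filled
#' with that first observation, since forward fill is undefined there. The
#' sample at time t represents the interval [t, t + step).
#'
#' @param raw A [raw_recording()].
#' @param step Grid interval in seconds (default 1).
#' @return A [feature_series()] of length `floor((last_t - first_t)/step) + 1`.
#' @export
regularize <- function(raw, step = 1) {
  if (!inherits(raw, "raw_recording")) stop_config("raw must be a raw_recording")
  rec <- raw$records
  t0 <- min(rec$t)
  t1 <- max(rec$t)
  n <- floor((t1 - t0) / step) + 1L
  grid <- t0 + (seq_len(n) - 1) * step
  vals <- vapply(raw$features, function(f) {
    sub <- rec[rec$feature == f & !is.na(rec$value), , drop = FALSE]
    # last observation with time <= grid point; 0 means "before first obs"
    idx <- findInterval(grid, sub$t)
    sub$value[pmax(idx, 1L)]
  }, numeric(n))
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, raw$features))
  feature_series(vals, start_time = t0, step = step)
}

#' Remove outliers from a regularized series
#'
#' The default is to leave the data untouched: the judgement of what counts
#' as an "obvious outlier" belongs to the analyst. The optional `mad` rule
#' automates it: per feature, points farther than `k` robust deviations
#' (median absolute deviation, scaled by 1.4826) from the median are marked
#' missing and re-filled by forward fill. When the MAD is zero (more than
#' half the samples identical) the rule degrades to flagging any value that
#' differs from the median, so a constant series is never altered.
#'
#' @param series A [feature_series()].
#' @param method `"none"` (default) or `"mad"`.
#' @param k Robust-deviation multiplier for the MAD rule.
#' @return A [feature_series()] of the same shape.
#' @export
remove_outliers <- function(series, method = c("none", "mad"), k = 5) {
  method <- match.arg(method)
  if (method == "none") return(series)
  v <- series$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    med <- stats::median(x)
    s <- stats::mad(x)
    out <- if (s > 0) abs(x - med) > k * s else abs(x - med) > 0
    if (any(out)) {
      x[out] <- NA_real_
      v[, j] <- forward_fill(x)
    }
  }
  feature_series(v, start_time = series$start_time, step = series$step)
}

#' Construct an event-point annotation
#'
#' Event points are the human-annotated moments at which the subject's face
#' visibly becomes happy looking (`happy_onset`) or stops looking happy
#' (`happy_offset`); they are the ground truth for recall/precision.
#'
#' @param time Event times in seconds.
#' @param polarity Labels, one of `"happy_onset"`, `"happy_offset"`.
#' @return Object of class `event_annotation` with elements `events`
#'   (data frame sorted by time) and `n_e`.
#' @export
event_annotation <- function(time = numeric(0), polarity = character(0)) {
  time <- as.numeric(time)
  polarity <- as.character(polarity)
  if (length(time) != length(polarity))
    stop_input("time and polarity must have equal length")
  bad <- setdiff(unique(polarity), c("happy_onset", "happy_offset"))
  if (length(bad))
    stop_input("unknown polarity label(s): %s", paste(bad, collapse = ", "))
  o <- order(time)
  time <- time[o]
  polarity <- polarity[o]
  if (anyDuplicated(time))
    stop_input("event times must be strictly increasing")
  structure(list(events = data.frame(time = time, polarity = polarity,
                                     stringsAsFactors = FALSE),
                 n_e = length(time)),
            class = "event_annotation")
}

#' @export
print.event_annotation <- function(x, ...) {
  cat(sprintf("<event_annotation> n_e=%d (%d onsets, %d offsets)\n", x$n_e,
              sum(x$events$polarity == "happy_onset"),
              sum(x$events$polarity == "happy_offset")))
  invisible(x)
}

#' Read an event-point CSV
#'
#' Expects header `t,polarity` with polarity in
#' `{happy_onset, happy_offset}`. An empty body yields an annotation with
#' `n_e = 0`.
#'
#' @param path Path to the CSV file.
#' @return An [event_annotation()].
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: '%s'", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("t", "polarity") %in% names(df)))
    stop_input("events file '%s' must have columns t and polarity", path)
  event_annotation(df$t, df$polarity)
}

#' Write a feature series back to CSV
#' @param series A [feature_series()].
#' @param path Output path; columns `t` plus one per feature.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write events to CSV
#' @param events An [event_annotation()].
#' @param path Output path with columns `t,polarity`.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(t = events$events$time, polarity = events$events$polarity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
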