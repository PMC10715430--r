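#' Construct a raw accelerometer recording
#'
#' The central in-memory container of the package: a uniformly sampled
#' tri-axial acceleration time series in gravitational units (g), with an
#' optional aligned near-body temperature channel.
#'
#' @param time numeric vector of timestamps in seconds since the Unix epoch,
#'   strictly increasing on a uniform grid (within the gap tolerance).
#' @param acc numeric matrix with one row per sample and three columns
#'   (x, y, z) in g.
#' @param temperature optional numeric vector (degrees Celsius), aligned 1:1
#'   with \code{time}.
#' @param sampling_rate sampling frequency in Hz. If \code{NULL} it is
#'   inferred from the median timestamp spacing.
#' @param tz_offset offset in seconds added to \code{time} to obtain local
#'   civil time; used only for day segmentation.
#' @param range_g declared sensor range in g (default 8).
#' @param gap_tol multiple of the nominal sample spacing above which a
#'   timestamp step is treated as a recording gap (default 1.5). Gaps are
#'   recorded in the \code{gaps} field and later treated as non-wear.
#'
#' @return An object of class \code{raw_recording}: a list with fields
#'   \code{time}, \code{acc}, \code{temperature}, \code{sampling_rate},
#'   \code{tz_offset}, \code{range_g} and \code{gaps} (two-column matrix of
#'   gap start/stop times, possibly empty).
#' @export
raw_recording <- function(time, acc, temperature = NULL, sampling_rate = NULL,
                          tz_offset = 0, range_g = 8, gap_tol = 1.5) {
  time <- as.numeric(time)
  acc <- as.matrix(acc)
  storage.mode(acc) <- "double"
  n <- length(time)
  if (n < 1L) stop("recording is empty", call. = FALSE)
  if (nrow(acc) != n || ncol(acc) != 3L)
    stop("acc must be an n x 3 matrix aligned with time", call. = FALSE)
  dt <- diff(time)
  if (n > 1L && any(dt <= 0))
    stop("timestamps must be strictly increasing (duplicate or reversed timestamps found)",
         call. = FALSE)
  if (is.null(sampling_rate)) {
    if (n < 2L) stop("cannot infer sampling_rate from a single sample", call. = FALSE)
    sampling_rate <- 1 / stats::median(dt)
  }
  if (!all(is.finite(acc)))
    stop("acceleration contains non-finite values", call. = FALSE)
  if (max(abs(acc)) > range_g)
    stop(sprintf("acceleration exceeds declared range of %.3g g", range_g),
         call. = FALSE)
  if (!is.null(temperature)) {
    temperature <- as.numeric(temperature)
    if (length(temperature) != n)
      stop("temperature must align 1:1 with timestamps", call. = FALSE)
  }
  # steps wider than gap_tol sample intervals are recording gaps
  gaps <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "stop")))
  if (n > 1L) {
    gi <- which(dt > gap_tol / sampling_rate)
    if (length(gi))
      gaps <- cbind(start = time[gi], stop = time[gi + 1L])
  }
  structure(list(time = time, acc = acc, temperature = temperature,
                 sampling_rate = sampling_rate, tz_offset = tz_offset,
                 range_g = range_g, gaps = gaps),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- (x$time[length(x$time)] - x$time[1]) / 3600
  cat(sprintf("<raw_recording> %d samples @ %.4g Hz (%.2f h)%s, %d gap(s)\n",
              length(x$time), x$sampling_rate, dur,
              if (is.null(x$temperature)) "" else " + temperature",
              nrow(x$gaps)))
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Reads a CSV of raw wrist accelerometry with columns \code{time} (ISO-8601
#' or numeric epoch seconds), \code{ax}, \code{ay}, \code{az} in g and an
#' optional \code{temp} column in degrees Celsius. Column names can be
#' remapped through \code{col_map}.
#'
#' @param path path to the delimited text file.
#' @param delimiter field separator (default comma).
#' @param col_map named character vector mapping the canonical names
#'   \code{time}, \code{ax}, \code{ay}, \code{az}, \code{temp} to the file's
#'   column names.
#' @param tz_offset,sampling_rate,range_g,gap_tol passed to
#'   \code{\link{raw_recording}}.
#' @return A \code{\link{raw_recording}}.
#' @export
read_recording <- function(path, delimiter = ",",
                           col_map = c(time = "time", ax = "ax", ay = "ay",
                                       az = "az", temp = "temp"),
                           tz_offset = 0, sampling_rate = NULL, range_g = 8,
                           gap_tol = 1.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "ax", "ay", "az")
  cols <- col_map[need]
  missing_cols <- cols[!cols %in% names(df)]
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tm <- df[[cols[["time"]]]]
  if (!is.numeric(tm)) {
    tm <- as.numeric(as.POSIXct(as.character(tm), tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS")))
    if (anyNA(tm)) stop("unparseable timestamps", call. = FALSE)
  }
  acc <- cbind(df[[cols[["ax"]]]], df[[cols[["ay"]]]], df[[cols[["az"]]]])
  tcol <- if ("temp" %in% names(col_map)) col_map[["temp"]] else "temp"
  temperature <- if (tcol %in% names(df)) df[[tcol]] else NULL
  raw_recording(tm, acc, temperature = temperature,
                sampling_rate = sampling_rate, tz_offset = tz_offset,
                range_g = range_g, gap_tol = gap_tol)
}

#' Write a recording to CSV
#'
#' Inverse of \code{\link{read_recording}} at the declared precision.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param path output path.
#' @param digits significant digits for acceleration/temperature.
#' @export
write_recording <- function(rec, path, digits = 6) {
  df <- data.frame(time = rec$time,
                   ax = signif(rec$acc[, 1], digits),
                   ay = signif(rec$acc[, 2], digits),
                   az = signif(rec$acc[, 3], digits))
  if (!is.null(rec$temperature)) df$temp <- signif(rec$temperature, digits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a labelled interval set
#'
#' Ordered, half-open \code{[start, stop)} intervals labelled with wear,
#' non-wear, sleep or wake status. Intervals sharing a label must not
#' overlap.
#'
#' @param start,stop numeric vectors of interval boundaries in epoch seconds.
#' @param label character vector of labels, each one of \code{"wear"},
#'   \code{"nonwear"}, \code{"sleep"}, \code{"wake"}.
#' @return A data frame of class \code{interval_set} with columns
#'   \code{start}, \code{stop}, \code{label}, sorted by start time.
#' @export
interval_set <- function(start = numeric(0), stop = numeric(0),
                         label = character(0)) {
  start <- as.numeric(start); stop <- as.numeric(stop)
  label <- as.character(label)
  if (length(start) != length(stop) || length(start) != length(label))
    stop("start, stop and label must have equal length", call. = FALSE)
  ok <- label %in% c("wear", "nonwear", "sleep", "wake")
  if (!all(ok))
    stop("unknown interval label(s): ", paste(unique(label[!ok]), collapse = ", "),
         call. = FALSE)
  if (any(stop <= start))
    stop("every interval stop must exceed its start", call. = FALSE)
  o <- order(start, stop)
  df <- data.frame(start = start[o], stop = stop[o], label = label[o],
                   stringsAsFactors = FALSE)
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$stop[-nrow(sub)]))
      stop("overlapping intervals within label '", lab, "'", call. = FALSE)
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Subset an interval set by label
#' @param x an \code{\link{interval_set}}.
#' @param label label(s) to keep.
#' @return An \code{interval_set} containing only the requested labels.
#' @export
interval_filter <- function(x, label) {
  interval_set(x$start[x$label %in% label], x$stop[x$label %in% label],
               x$label[x$label %in% label])
}

#' Total overlap between intervals and a time range, in seconds
#' @param x an \code{\link{interval_set}} (typically already filtered to one
#'   label).
#' @param range_start,range_stop the clipping range in epoch seconds.
#' @return Overlap duration in seconds.
#' @export
interval_overlap_s <- function(x, range_start, range_stop) {
  if (nrow(x) == 0L) return(0)
  lo <- pmax(x$start, range_start)
  hi <- pmin(x$stop, range_stop)
  sum(pmax(hi - lo, 0))
}

#' Membership of time points in an interval set
#' @param t numeric vector of times (epoch seconds).
#' @param x an \code{\link{interval_set}}.
#' @return Logical vector: is each time inside some interval of \code{x}
#'   (half-open convention)?
#' @export
in_intervals <- function(t, x) {
  if (nrow(x) == 0L) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(x)))
    res <- res | (t >= x$start[i] & t < x$stop[i])
  res
}

#' Collapse a logical per-sample mask into intervals
#'
#' Helper used by the wear and sleep detectors: converts a per-window logical
#' vector plus window start times into merged \code{[start, stop)} intervals.
#'
#' @param mask logical vector.
#' @param t numeric vector of window start times (same length).
#' @param step window length in seconds (stop of window i is \code{t[i] + step}).
#' @param label label for TRUE runs.
#' @return An \code{\link{interval_set}} (possibly empty) covering TRUE runs.
#' @export
mask_to_intervals <- function(mask, t, step, label) {
  if (!length(mask) || !any(mask)) return(interval_set())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  interval_set(t[starts[keep]], t[ends[keep]] + step,
               rep(label, length(keep)))
}

#' Load labelled intervals from CSV
#' @param path CSV with columns \code{start}, \code{stop} (epoch seconds or
#'   ISO-8601) and optionally \code{label}.
#' @param default_label label applied when the file has no label column.
#' @return An \code{\link{interval_set}}.
#' @export
read_intervals <- function(path, default_label = "sleep") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(interval_set())
  if (!all(c("start", "stop") %in% names(df)))
    stop("interval file needs 'start' and 'stop' columns", call. = FALSE)
  parse_t <- function(v) {
    if (is.numeric(v)) return(as.numeric(v))
    as.numeric(as.POSIXct(as.character(v), tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS")))
  }
  lab <- if ("label" %in% names(df)) df$label else rep(default_label, nrow(df))
  interval_set(parse_t(df$start), parse_t(df$stop), lab)
}

#' Write an interval set to CSV
#' @param x an \code{\link{interval_set}}.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Segment a recording into calendar days
#'
#' Partitions the samples into local civil days. The default convention is
#' midnight-to-midnight in the recording's local time (anchor hour 0);
#' partial first and last days are kept (the daily wear-time gate drops
#' short days later).
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param anchor_hour hour of day (0-23) at which days begin.
#' @return Data frame with one row per day: \code{date} (Date of the day
#'   start), \code{start_idx}, \code{end_idx} (inclusive sample index range),
#'   \code{day_start}, \code{day_stop} (epoch seconds of the civil-day
#'   boundaries).
#' @export
segment_days <- function(rec, anchor_hour = 0) {
  local <- rec$time + rec$tz_offset - anchor_hour * 3600
  day <- floor(local / 86400)
  idx <- which(diff(day) != 0)
  starts <- c(1L, idx + 1L)
  ends <- c(idx, length(day))
  data.frame(
    date = as.Date(day[starts], origin = "1970-01-01"),
    start_idx = starts, end_idx = ends,
    day_start = (day[starts]) * 86400 - rec$tz_offset + anchor_hour * 3600,
    day_stop = (day[starts] + 1) * 86400 - rec$tz_offset + anchor_hour * 3600
  )
}

#' Write daily endpoint rows to a tidy CSV
#'
#' One row per subject-day-period; metric columns are the union over rows in
#' stable (first-seen) order, missing cells left empty. Round-trips through
#' \code{\link{read_endpoints}} at the declared precision.
#'
#' @param rows list of daily endpoint rows, each a list with fields
#'   \code{subject}, \code{date}, \code{period}, \code{wear_h} and
#'   \code{metrics} (named numeric vector), or a data frame in the same
#'   layout.
#' @param path output path.
#' @param digits significant digits written (default 10).
#' @return The output path, invisibly.
#' @export
write_endpoints <- function(rows, path, digits = 10) {
  if (is.data.frame(rows)) {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  metric_names <- character(0)
  for (r in rows) metric_names <- union(metric_names, names(r$metrics))
  header <- c("subject", "date", "period", "wear_h", metric_names)
  out <- lapply(rows, function(r) {
    vals <- rep(NA_real_, length(metric_names))
    names(vals) <- metric_names
    vals[names(r$metrics)] <- r$metrics
    data.frame(subject = r$subject, date = as.character(r$date),
               period = r$period, wear_h = r$wear_h,
               as.list(signif(vals, digits)), check.names = FALSE)
  })
  df <- if (length(out)) do.call(rbind, out) else
    stats::setNames(data.frame(matrix(ncol = length(header), nrow = 0)), header)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a daily endpoint table written by \code{\link{write_endpoints}}
#' @param path CSV path.
#' @return Data frame with columns \code{subject}, \code{date},
#'   \code{period}, \code{wear_h} and one column per metric.
#' @export
read_endpoints <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
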