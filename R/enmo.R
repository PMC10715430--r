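#' ENMO pipeline parameters
#'
#' \code{wlen} is the non-overlapping averaging window for the epoch series
#' (5 s), and \code{thresh_wear} the daily wear-time gate (10 h): a day with
#' less wear contributes no epochs and hence no endpoints.
#'
#' @param wlen epoch window length in seconds (default 5).
#' @param thresh_wear daily wear gate in hours, in (0, 24] (default 10).
#' @param trim_at_zero clip negative ENMO values to zero (default TRUE).
#' @return A list of class \code{enmo_params}.
#' @export
enmo_params <- function(wlen = 5, thresh_wear = 10, trim_at_zero = TRUE) {
  stopifnot(wlen > 0, thresh_wear > 0, thresh_wear <= 24)
  structure(list(wlen = wlen, thresh_wear = thresh_wear,
                 trim_at_zero = trim_at_zero),
            class = "enmo_params")
}

#' Per-sample Euclidean Norm Minus One
#'
#' \eqn{ENMO(t) = \sqrt{a_x^2 + a_y^2 + a_z^2} - 1}, clipped at zero: the
#' residual acceleration magnitude after removing gravity, in g. A device
#' at rest in any orientation reads 0.
#'
#' @param acc n x 3 acceleration matrix in g.
#' @param trim_at_zero clip negative values to 0 (default TRUE).
#' @return Numeric vector of per-sample ENMO values in g.
#' @export
compute_enmo <- function(acc, trim_at_zero = TRUE) {
  acc <- as.matrix(acc)
  e <- sqrt(rowSums(acc^2)) - 1
  if (trim_at_zero) e <- pmax(e, 0)
  e
}

#' Windowed ENMO epoch series
#'
#' Non-overlapping moving mean of per-sample ENMO over \code{wlen}-second
#' windows (250 samples at 50 Hz and 5 s). A trailing partial window is
#' dropped.
#'
#' @param enmo per-sample ENMO vector (g).
#' @param sampling_rate sampling rate in Hz.
#' @param wlen window length in seconds.
#' @param t0 timestamp of the first sample (epoch seconds; default 0).
#' @return An object of class \code{epoch_series}: list with
#'   \code{epoch_start} (seconds), \code{values} (mean ENMO per epoch, g)
#'   and \code{epoch_length} (seconds).
#' @export
window_enmo <- function(enmo, sampling_rate, wlen = 5, t0 = 0) {
  spw <- as.integer(round(wlen * sampling_rate))
  if (spw < 1L) stop("wlen shorter than one sample", call. = FALSE)
  nwin <- length(enmo) %/% spw
  if (nwin < 1L) stop("fewer samples than one full window", call. = FALSE)
  keep <- nwin * spw
  vals <- colMeans(matrix(enmo[seq_len(keep)], nrow = spw))
  epoch_series(t0 + (seq_len(nwin) - 1L) * wlen, vals, wlen)
}

#' Construct an epoch series
#' @param epoch_start epoch start times in seconds.
#' @param values mean ENMO per epoch in g (non-negative when trimmed).
#' @param epoch_length epoch length in seconds.
#' @return An \code{epoch_series} object.
#' @export
epoch_series <- function(epoch_start, values, epoch_length) {
  stopifnot(length(epoch_start) == length(values), epoch_length > 0)
  structure(list(epoch_start = as.numeric(epoch_start),
                 values = as.numeric(values),
                 epoch_length = as.numeric(epoch_length)),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d epochs of %g s, mean %.4f g\n",
              length(x$values), x$epoch_length,
              if (length(x$values)) mean(x$values) else NA_real_))
  invisible(x)
}

#' Concatenate epoch series (same epoch length)
#' @param ... epoch_series objects.
#' @return A single \code{epoch_series}.
#' @export
concat_epochs <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(NULL)
  el <- unique(vapply(parts, function(p) p$epoch_length, numeric(1)))
  stopifnot(length(el) == 1L)
  epoch_series(unlist(lapply(parts, `[[`, "epoch_start")),
               unlist(lapply(parts, `[[`, "values")), el)
}

#' Per-day, wear-gated, wake/sleep-split ENMO epochs
#'
#' The daily driver: for each calendar day, non-wear samples are removed;
#' the day is skipped entirely when the remaining wear time is below the
#' 10 h gate; the surviving samples are split at the sleep boundaries into
#' wake and sleep periods; and windowed ENMO is computed per period.
#' Windows never span removed segments: epoching restarts at every
#' contiguous run of retained samples, so no epoch mixes non-adjacent data.
#'
#' @param rec a (calibrated) \code{\link{raw_recording}}.
#' @param wear an \code{\link{interval_set}} with wear/nonwear labels, or
#'   \code{NULL} to treat the whole recording as worn.
#' @param sleep an \code{\link{interval_set}} of sleep intervals, or
#'   \code{NULL} for no wake/sleep split (everything is wake).
#' @param params an \code{\link{enmo_params}}.
#' @param anchor_hour day-boundary hour passed to
#'   \code{\link{segment_days}}.
#' @return A data-frame-backed list of class \code{day_epochs}: one element
#'   per retained (day, period) with fields \code{date}, \code{period}
#'   ("wake" or "sleep"), \code{wear_h}, and \code{epochs}
#'   (an \code{epoch_series}). Days failing the wear gate are absent.
#' @export
run_day_pipeline <- function(rec, wear = NULL, sleep = NULL,
                             params = enmo_params(), anchor_hour = 0) {
  fs <- rec$sampling_rate
  days <- segment_days(rec, anchor_hour = anchor_hour)
  if (is.null(wear))
    wear <- interval_set(rec$time[1], rec$time[length(rec$time)] + 1 / fs,
                         "wear")
  worn <- in_intervals(rec$time, interval_filter(wear, "wear"))
  asleep <- if (is.null(sleep)) rep(FALSE, length(rec$time)) else
    in_intervals(rec$time, interval_filter(sleep, "sleep"))
  enmo_all <- compute_enmo(rec$acc, trim_at_zero = params$trim_at_zero)

  out <- list()
  for (d in seq_len(nrow(days))) {
    idx <- days$start_idx[d]:days$end_idx[d]
    t_wear <- wear_time(wear, days$day_start[d], days$day_stop[d])
    if (t_wear < params$thresh_wear) next
    for (period in c("wake", "sleep")) {
      sel <- idx[worn[idx] & (asleep[idx] == (period == "sleep"))]
      if (!length(sel)) next
      ser <- .epoch_contiguous(enmo_all, rec$time, sel, fs, params$wlen)
      if (is.null(ser) || !length(ser$values)) next
      out[[length(out) + 1L]] <- list(date = days$date[d], period = period,
                                      wear_h = t_wear, epochs = ser)
    }
  }
  structure(out, class = "day_epochs")
}

# epoch the selected sample indices, restarting at each contiguous run
.epoch_contiguous <- function(enmo, time, sel, fs, wlen) {
  if (!length(sel)) return(NULL)
  # runs of consecutive indices with no timestamp gap
  brk <- which(diff(sel) != 1L | diff(time[sel]) > 1.5 / fs)
  run_start <- c(1L, brk + 1L)
  run_end <- c(brk, length(sel))
  parts <- list()
  spw <- as.integer(round(wlen * fs))
  for (r in seq_along(run_start)) {
    ii <- sel[run_start[r]:run_end[r]]
    if (length(ii) < spw) next
    parts[[length(parts) + 1L]] <-
      window_enmo(enmo[ii], fs, wlen, t0 = time[ii[1]])
  }
  if (!length(parts)) return(NULL)
  do.call(concat_epochs, parts)
}
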