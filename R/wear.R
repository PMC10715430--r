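#' Wear-detection parameters
#'
#' Defaults follow the published temperature-augmented non-wear algorithm
#' configuration for wrist devices: acceleration standard-deviation
#' threshold 0.008 g, low/high temperature thresholds 26.0/30.0 degrees C,
#' temperature rate-of-decrease threshold -0.2 degrees C/min,
#' rate-of-increase threshold 0.1 degrees C/min, and a 1 s classification
#' window. \code{min_wear_gate} is the daily wear-time gate (10 h) applied
#' downstream.
#'
#' @param acc_sd_thresh acceleration SD threshold in g.
#' @param temp_low,temp_high temperature thresholds in degrees C.
#' @param temp_dec_rate,temp_inc_rate temperature slope thresholds in
#'   degrees C per minute (decrease negative, increase positive).
#' @param window_s classification window in seconds.
#' @param min_wear_gate daily wear gate in hours.
#' @return A list of class \code{wear_params}.
#' @export
wear_params <- function(acc_sd_thresh = 0.008, temp_low = 26.0,
                        temp_high = 30.0, temp_dec_rate = -0.2,
                        temp_inc_rate = 0.1, window_s = 1,
                        min_wear_gate = 10) {
  stopifnot(temp_low < temp_high, temp_dec_rate < 0, temp_inc_rate > 0,
            window_s > 0)
  structure(list(acc_sd_thresh = acc_sd_thresh, temp_low = temp_low,
                 temp_high = temp_high, temp_dec_rate = temp_dec_rate,
                 temp_inc_rate = temp_inc_rate, window_s = window_s,
                 min_wear_gate = min_wear_gate),
            class = "wear_params")
}

# non-overlapping window means/SDs of a vector; returns list(mean, sd, t0)
.windowed_stats <- function(x, t, wlen) {
  n <- length(x)
  nwin <- n %/% wlen
  keep <- nwin * wlen
  m <- matrix(x[seq_len(keep)], nrow = wlen)
  mu <- colMeans(m)
  sd <- sqrt(pmax(colMeans(m^2) - mu^2, 0) * wlen / max(wlen - 1, 1))
  list(mean = mu, sd = sd, t0 = t[seq(1, keep, by = wlen)])
}

# centred rolling linear slope of y (per index step), half-width h
.rolling_slope <- function(y, h) {
  n <- length(y)
  k <- 2L * h + 1L
  if (n < k) return(rep(0, n))
  x <- seq(-h, h)
  denom <- sum(x^2)
  num <- stats::filter(y, rev(x), sides = 2)  # sum x_i * y_{t+i}
  sl <- as.numeric(num) / denom
  sl[is.na(sl)] <- 0
  sl
}

# rolling median, odd window k, edges filled with nearest value
.rolling_median <- function(y, k) {
  n <- length(y)
  if (n < k) return(y)
  h <- k %/% 2L
  out <- y
  out[(h + 1L):(n - h)] <- stats::runmed(y, k)[(h + 1L):(n - h)]
  out
}

#' Detect non-wear from acceleration variance and temperature
#'
#' Classifies each 1 s window as worn or doffed from three signals: the
#' maximum per-axis acceleration standard deviation, the smoothed near-body
#' temperature (1 min moving median), and the temperature slope (centred
#' linear fit over 5 min, in degrees C/min). A window is non-wear when the
#' temperature is below \code{temp_low} while the device is still
#' (SD below \code{acc_sd_thresh}); a sustained temperature decrease
#' (slope at or below \code{temp_dec_rate}) leading into such a period
#' extends the non-wear onset backwards to the start of the decrease, and a
#' sustained increase (slope at or above \code{temp_inc_rate}) or
#' temperature above \code{temp_high} re-labels wear. Gap-derived non-wear
#' recorded on the recording is unioned in.
#'
#' @param rec a \code{\link{raw_recording}} with a temperature channel.
#' @param params a \code{\link{wear_params}}.
#' @return An \code{\link{interval_set}} whose wear and nonwear intervals
#'   partition the recording span at 1 s resolution.
#' @export
detect_wear <- function(rec, params = wear_params()) {
  if (is.null(rec$temperature))
    stop("temperature channel required; use detect_wear_acc_only() for accelerometer-only recordings",
         call. = FALSE)
  fs <- rec$sampling_rate
  wlen <- max(1L, as.integer(round(params$window_s * fs)))
  sds <- sapply(1:3, function(j) .windowed_stats(rec$acc[, j], rec$time, wlen)$sd)
  ws <- .windowed_stats(rec$temperature, rec$time, wlen)
  acc_sd <- apply(as.matrix(sds), 1, max)
  t0 <- ws$t0
  step <- params$window_s
  # temperature smoothing: 1 min moving median, slope over 5 min centred fit
  k_med <- max(3L, 2L * as.integer(30 / step) + 1L)
  if (k_med > length(ws$mean))
    k_med <- max(1L, length(ws$mean) - (1L - length(ws$mean) %% 2L))
  temp_sm <- if (k_med >= 3L) .rolling_median(ws$mean, k_med) else ws$mean
  h <- as.integer(150 / step)                  # 2.5 min half-width
  slope <- .rolling_slope(temp_sm, h) * 60 / step   # degC per minute
  still <- acc_sd < params$acc_sd_thresh
  base_nw <- temp_sm < params$temp_low & still

  nw <- base_nw
  # extend non-wear onset back through the sustained temperature decrease
  dec <- slope <= params$temp_dec_rate & still
  r <- rle(nw)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (b in which(r$values)) {
    i <- starts[b] - 1L
    while (i >= 1L && dec[i]) { nw[i] <- TRUE; i <- i - 1L }
  }
  # re-label wear on sustained temperature increase (once back above the
  # low threshold) or on high temperature that is not actively falling --
  # a freshly doffed device still reads warm while its temperature drops
  rewarm <- (slope >= params$temp_inc_rate & temp_sm >= params$temp_low) |
    (temp_sm > params$temp_high & slope >= 0)
  nw[rewarm] <- FALSE

  iv_nw <- mask_to_intervals(nw, t0, step, "nonwear")
  # union gap-derived non-wear
  if (nrow(rec$gaps) > 0L)
    iv_nw <- .union_nonwear(iv_nw, rec$gaps)
  .complement_wear(iv_nw, rec$time[1], rec$time[length(rec$time)] + 1 / fs)
}

# union nonwear intervals with gap matrix, merging overlaps
.union_nonwear <- function(iv, gaps) {
  st <- c(iv$start, gaps[, 1]); sp <- c(iv$stop, gaps[, 2])
  if (!length(st)) return(interval_set())
  o <- order(st)
  st <- st[o]; sp <- sp[o]
  out_s <- st[1]; out_e <- sp[1]
  if (length(st) > 1L) for (i in 2:length(st)) {
    if (st[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], sp[i])
    } else {
      out_s <- c(out_s, st[i]); out_e <- c(out_e, sp[i])
    }
  }
  interval_set(out_s, out_e, rep("nonwear", length(out_s)))
}

# complement of nonwear intervals over [t0, t1) labelled wear
.complement_wear <- function(iv_nw, t0, t1) {
  if (nrow(iv_nw) == 0L)
    return(interval_set(t0, t1, "wear"))
  s <- pmax(pmin(iv_nw$start, t1), t0)
  e <- pmax(pmin(iv_nw$stop, t1), t0)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(interval_set(t0, t1, "wear"))
  ws <- c(t0, e); we <- c(s, t1)
  keep <- we > ws
  interval_set(c(s, ws[keep]), c(e, we[keep]),
               c(rep("nonwear", length(s)), rep("wear", sum(keep))))
}

#' Accelerometer-only non-wear detection
#'
#' Long-window fallback for recordings without a temperature channel:
#' 60 min windows advanced in 15 min steps; a window qualifies as non-wear
#' when at least two axes have standard deviation below \code{sd_thresh}
#' and value range below \code{range_thresh}, and the non-wear mask is the
#' union of all qualifying windows (resolution one step). Short wear
#' fragments (under 30 min) sandwiched between long (over 60 min) non-wear
#' blocks are absorbed into non-wear.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param window_min window length in minutes (default 60).
#' @param step_min step length in minutes (default 15).
#' @param sd_thresh per-axis SD threshold in g (default 0.013).
#' @param range_thresh per-axis range threshold in g (default 0.050).
#' @return An \code{\link{interval_set}} partitioning the recording into
#'   wear and nonwear.
#' @export
detect_wear_acc_only <- function(rec, window_min = 60, step_min = 15,
                                 sd_thresh = 0.013, range_thresh = 0.050) {
  fs <- rec$sampling_rate
  n <- nrow(rec$acc)
  step <- as.integer(round(step_min * 60 * fs))
  win <- as.integer(round(window_min * 60 * fs))
  starts <- seq(1L, max(n - step + 1L, 1L), by = step)
  nsteps <- length(starts)
  steps_per_win <- max(1L, win %/% step)
  nw <- logical(nsteps)
  for (k in seq_len(nsteps)) {
    lo <- starts[k]
    hi <- min(n, lo + win - 1L)
    if (hi - lo + 1L < win %/% 2L) next    # ignore stub windows at the end
    seg <- rec$acc[lo:hi, , drop = FALSE]
    crit <- vapply(1:3, function(j) {
      v <- seg[, j]
      stats::sd(v) < sd_thresh && (max(v) - min(v)) < range_thresh
    }, logical(1))
    if (sum(crit) >= 2L)                   # whole window is non-wear
      nw[k:min(nsteps, k + steps_per_win - 1L)] <- TRUE
  }
  # absorb short wear sandwiched between long non-wear
  r <- rle(nw)
  if (length(r$lengths) >= 3L) {
    blocks_min <- r$lengths * step_min
    for (b in 2:(length(r$lengths) - 1L)) {
      if (!r$values[b] && blocks_min[b] < 30 &&
          r$values[b - 1L] && blocks_min[b - 1L] >= 60 &&
          r$values[b + 1L] && blocks_min[b + 1L] >= 60)
        r$values[b] <- TRUE
    }
    nw <- inverse.rle(r)
  }
  t0 <- rec$time[starts]
  # last block runs to the end of the recording
  stops <- c(t0[-1L], rec$time[n] + 1 / fs)
  iv_nw <- if (any(nw)) {
    keep <- which(nw)
    .union_nonwear(interval_set(t0[keep], stops[keep],
                                rep("nonwear", length(keep))),
                   rec$gaps)
  } else if (nrow(rec$gaps)) {
    .union_nonwear(interval_set(), rec$gaps)
  } else interval_set()
  .complement_wear(iv_nw, rec$time[1], rec$time[n] + 1 / fs)
}

#' Wear time within a day, in hours
#'
#' Total duration of wear intervals intersected with a day range. Feeds the
#' daily wear-time gate: days under 10 h of wear contribute no endpoints.
#'
#' @param intervals an \code{\link{interval_set}} containing wear labels.
#' @param day_start,day_stop day range in epoch seconds.
#' @return Wear hours (numeric scalar).
#' @export
wear_time <- function(intervals, day_start, day_stop) {
  interval_overlap_s(interval_filter(intervals, "wear"),
                     day_start, day_stop) / 3600
}
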