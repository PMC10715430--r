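#' Sleep-detection parameters
#'
#' Defaults for the wrist-angle heuristic: 5 s angle epochs, 5 degree
#' rolling angle-change threshold, 30 min minimum inactive block, and a
#' 25 degree C temperature veto (a candidate sleep window colder than this
#' is judged to be a doffed device, not a sleeping wearer).
#'
#' @param angle_epoch_s angle epoch length in seconds.
#' @param angle_change_thresh rolling absolute angle-change threshold in
#'   degrees.
#' @param min_block_min minimum inactive block length in minutes.
#' @param temp_veto temperature veto in degrees C.
#' @return A list of class \code{sleep_params}.
#' @export
sleep_params <- function(angle_epoch_s = 5, angle_change_thresh = 5,
                         min_block_min = 30, temp_veto = 25) {
  stopifnot(angle_epoch_s > 0, angle_change_thresh > 0, min_block_min > 0,
            temp_veto > 0)
  structure(list(angle_epoch_s = angle_epoch_s,
                 angle_change_thresh = angle_change_thresh,
                 min_block_min = min_block_min, temp_veto = temp_veto),
            class = "sleep_params")
}

#' Estimate the major sleep period per day
#'
#' Heuristic sleep detection from wrist posture: the z-angle
#' \eqn{atan2(a_z, \sqrt{a_x^2 + a_y^2})} is computed per 5 s epoch
#' (median over samples, then 5-epoch median smoothing); an epoch is
#' "inactive" when no absolute successive angle change within the
#' surrounding 5 min window reaches the threshold, i.e. the posture has
#' not changed for 5 minutes. Within each noon-to-noon window the longest
#' run of inactive blocks (at least \code{min_block_min} long, gaps under
#' 60 min bridged) becomes the candidate sleep period. Candidates
#' overlapping detected non-wear, or whose mean temperature is below the
#' veto, are discarded. At most one major sleep period is produced per
#' noon-to-noon day; naps are out of scope.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param wear an \code{\link{interval_set}} from a wear detector, used to
#'   veto candidates overlapping non-wear. May be \code{NULL}.
#' @param params a \code{\link{sleep_params}}.
#' @return An \code{\link{interval_set}} of sleep intervals (possibly
#'   empty; days with no candidate are simply all wake).
#' @export
estimate_sleep <- function(rec, wear = NULL, params = sleep_params()) {
  fs <- rec$sampling_rate
  ep <- max(1L, as.integer(round(params$angle_epoch_s * fs)))
  n <- nrow(rec$acc)
  nep <- n %/% ep
  if (nep < 2L) return(interval_set())
  keep <- nep * ep
  med_axis <- function(j)
    apply(matrix(rec$acc[seq_len(keep), j], nrow = ep), 2, stats::median)
  ax <- med_axis(1); ay <- med_axis(2); az <- med_axis(3)
  angle <- atan2(az, sqrt(ax^2 + ay^2)) * 180 / pi
  if (nep >= 5L) angle <- .rolling_median(angle, 5L)
  dchange <- c(abs(diff(angle)), 0)
  # inactive = no posture change >= thresh anywhere in the 5 min window
  k <- max(1L, as.integer(round(300 / params$angle_epoch_s)))
  big <- as.numeric(dchange >= params$angle_change_thresh)
  roll <- as.numeric(stats::filter(big, rep(1, k), sides = 2))
  roll[is.na(roll)] <- big[is.na(roll)]
  inactive <- roll == 0
  t0 <- rec$time[seq(1, keep, by = ep)]
  step <- params$angle_epoch_s

  # candidate blocks of inactivity; very short blips (< 10 min) are noise
  blocks <- mask_to_intervals(inactive, t0, step, "sleep")
  if (nrow(blocks) == 0L) return(interval_set())
  blocks <- blocks[(blocks$stop - blocks$start) >= 600, , drop = FALSE]
  if (nrow(blocks) == 0L) return(interval_set())

  # noon-to-noon search windows
  local <- rec$time[1] + rec$tz_offset
  first_noon <- (floor((local - 43200) / 86400)) * 86400 + 43200 - rec$tz_offset
  t_end <- rec$time[n]
  noons <- seq(first_noon, t_end + 86400, by = 86400)
  nonwear <- if (is.null(wear)) interval_set() else
    interval_filter(wear, "nonwear")

  out_s <- numeric(0); out_e <- numeric(0)
  for (w in seq_len(length(noons) - 1L)) {
    lo <- noons[w]; hi <- noons[w + 1L]
    bs <- pmax(blocks$start, lo); be <- pmin(blocks$stop, hi)
    sel <- which(be > bs)
    if (!length(sel)) next
    # bridge gaps < 60 min between successive blocks, then take longest run
    bs <- bs[sel]; be <- be[sel]
    runs <- 1L; run_id <- integer(length(bs)); run_id[1] <- 1L
    if (length(bs) > 1L) for (i in 2:length(bs)) {
      if (bs[i] - be[i - 1L] < 3600) run_id[i] <- run_id[i - 1L]
      else { runs <- runs + 1L; run_id[i] <- runs }
    }
    spans <- vapply(seq_len(runs), function(r)
      max(be[run_id == r]) - min(bs[run_id == r]), numeric(1))
    best <- which.max(spans)
    cs <- min(bs[run_id == best]); ce <- max(be[run_id == best])
    if (ce - cs < params$min_block_min * 60) next
    # vetoes: overlap with non-wear; uncharacteristically low temperature
    if (interval_overlap_s(nonwear, cs, ce) > 0) next
    if (!is.null(rec$temperature)) {
      sel_t <- rec$time >= cs & rec$time < ce
      if (mean(rec$temperature[sel_t]) < params$temp_veto) next
    }
    out_s <- c(out_s, cs); out_e <- c(out_e, ce)
  }
  if (!length(out_s)) return(interval_set())
  interval_set(out_s, out_e, rep("sleep", length(out_s)))
}

#' Load externally supplied sleep intervals
#'
#' @param path CSV with columns \code{start}, \code{stop} (epoch seconds or
#'   ISO-8601); any label column is overridden with "sleep".
#' @return An \code{\link{interval_set}} with label sleep; overlapping rows
#'   are a data error.
#' @export
load_sleep <- function(path) {
  iv <- read_intervals(path, default_label = "sleep")
  if (nrow(iv) == 0L) return(iv)
  interval_set(iv$start, iv$stop, rep("sleep", nrow(iv)))
}
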