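#' Process one recording into daily physical activity endpoints
#'
#' The full chain: autocalibration, non-wear detection (temperature-based
#' when a temperature channel is present, accelerometer-only otherwise or
#' on request), sleep-window estimation (or externally supplied sleep
#' intervals), wear-gated per-day ENMO epoching split at sleep boundaries,
#' and the endpoint battery (time in levels, bouted MVPA, maximum windowed
#' acceleration, intensity gradient) plus fragmentation metrics on each
#' wake period.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param subject subject identifier attached to the output rows.
#' @param calibrate run autocalibration first (default TRUE).
#' @param wear_method \code{"auto"} (temperature-based when available),
#'   \code{"detach"}, \code{"acc"}, or \code{"none"}.
#' @param sleep an \code{\link{interval_set}} of externally supplied sleep
#'   intervals; \code{NULL} (default) estimates them from the recording.
#' @param enmo an \code{\link{enmo_params}}.
#' @param cuts a \code{\link{cut_points}}.
#' @param anchor_hour day-boundary hour.
#' @return A data frame with one row per retained (day, period): columns
#'   \code{subject}, \code{date}, \code{period}, \code{wear_h} and one
#'   column per endpoint. Sleep-period rows carry only mean ENMO and time
#'   in levels; the full battery is computed on wake periods.
#' @export
process_recording <- function(rec, subject = "S01", calibrate = TRUE,
                              wear_method = c("auto", "detach", "acc",
                                              "none"),
                              sleep = NULL, enmo = enmo_params(),
                              cuts = cut_points(), anchor_hour = 0) {
  wear_method <- match.arg(wear_method)
  if (calibrate) rec <- calibrate_recording(rec)$recording
  wear <- switch(wear_method,
    auto = if (is.null(rec$temperature)) detect_wear_acc_only(rec)
           else detect_wear(rec),
    detach = detect_wear(rec),
    acc = detect_wear_acc_only(rec),
    none = NULL)
  if (is.null(sleep))
    sleep <- estimate_sleep(rec, wear = wear)
  de <- run_day_pipeline(rec, wear = wear, sleep = sleep, params = enmo,
                         anchor_hour = anchor_hour)
  rows <- lapply(de, function(x) {
    metrics <- if (x$period == "wake") {
      c(compute_endpoints(x$epochs, cuts = cuts),
        fragmentation_metrics(x$epochs, cuts = cuts))
    } else {
      c(time_in_levels(x$epochs, cuts = cuts),
        mean_ENMO = mean(x$epochs$values))
    }
    c(list(subject = subject, date = as.character(x$date),
           period = x$period, wear_h = x$wear_h), as.list(metrics))
  })
  if (!length(rows)) {
    return(data.frame(subject = character(0), date = character(0),
                      period = character(0), wear_h = numeric(0)))
  }
  all_names <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_names, names(r))
    for (m in miss) r[[m]] <- NA_real_
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Subject-level averages of daily wake endpoints
#'
#' Averages each metric across a subject's retained wake days, the form in
#' which endpoints enter group-level statistics.
#'
#' @param daily data frame from \code{\link{process_recording}} (one or
#'   more subjects row-bound together).
#' @return Long data frame: \code{subject}, \code{metric}, \code{value}.
#' @export
summarize_subjects <- function(daily) {
  wake <- daily[daily$period == "wake", , drop = FALSE]
  mcols <- setdiff(names(wake), c("subject", "date", "period", "wear_h"))
  out <- do.call(rbind, lapply(split(wake, wake$subject), function(d) {
    data.frame(subject = d$subject[1], metric = mcols,
               value = vapply(mcols, function(m)
                 mean(d[[m]], na.rm = TRUE), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
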