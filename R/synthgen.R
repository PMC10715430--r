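#' Cohort profile for the free-living simulator
#'
#' Describes one group's multi-day wrist-recording conditions: recording
#' length and rate, nightly sleep, the semi-Markov daytime activity process
#' (alternating SLPA/MVPA super-states with exponential dwell times, split
#' into the four cut-point levels by sub-state dwells), daily non-wear
#' behaviour, the temperature channel, sensor miscalibration and noise.
#' Dwell times are exponential so fragmentation metrics have analytic
#' expectations: the per-minute transition probability out of a state is
#' the reciprocal of its mean dwell.
#'
#' Defaults mirror the study conditions for healthy younger adults:
#' 7-day recordings at 50 Hz on a +/-8 g wrist device, ~8 h nightly sleep,
#' and state intensities straddling the 0.050/0.110/0.440 g cut-points.
#'
#' @param n_days number of recorded days.
#' @param sampling_rate Hz.
#' @param sleep_h_mean,sleep_h_sd nightly sleep duration (hours).
#' @param sleep_onset_h,sleep_onset_sd sleep onset clock hour and SD.
#' @param levels named mean ENMO per state in g (sedentary, light,
#'   moderate, vigorous); must be ordered and straddle the cut-points.
#' @param slpa_dwell_min,mvpa_dwell_min mean super-state dwell times in
#'   minutes.
#' @param sed_dwell_min,light_dwell_min,mod_dwell_min,vig_dwell_min mean
#'   sub-state dwells within a super-state bout, minutes.
#' @param nonwear_prob_day probability a given day contains a doffed block.
#' @param nonwear_dur_min mean doffed duration in minutes (exponential,
#'   clipped to [30, 240]).
#' @param temp_worn,temp_ambient worn and ambient temperatures, degrees C.
#' @param temp_tau_min exponential temperature time constant, minutes.
#' @param scale_range,offset_range per-axis ranges for the corrective
#'   calibration parameters planted in the recording (the generator applies
#'   their inverse to the true signal).
#' @param noise_sd per-axis acceleration noise SD in g.
#' @param posture_change_min mean minutes between sleep posture changes.
#' @return A list of class \code{cohort_profile}.
#' @export
cohort_profile <- function(n_days = 7, sampling_rate = 50,
                           sleep_h_mean = 8, sleep_h_sd = 0.5,
                           sleep_onset_h = 23, sleep_onset_sd = 0.5,
                           levels = c(sedentary = 0.02, light = 0.075,
                                      moderate = 0.18, vigorous = 0.55),
                           slpa_dwell_min = 22, mvpa_dwell_min = 2.4,
                           sed_dwell_min = 12, light_dwell_min = 2,
                           mod_dwell_min = 2, vig_dwell_min = 0.12,
                           nonwear_prob_day = 0.3, nonwear_dur_min = 90,
                           temp_worn = 34, temp_ambient = 21,
                           temp_tau_min = 10,
                           scale_range = c(1, 1), offset_range = c(0, 0),
                           noise_sd = 0.008, posture_change_min = 30) {
  cp <- cut_points()
  stopifnot(levels[["sedentary"]] < cp$sedentary_upper,
            levels[["light"]] >= cp$sedentary_upper,
            levels[["light"]] < cp$light_upper,
            levels[["moderate"]] >= cp$light_upper,
            levels[["moderate"]] < cp$moderate_upper,
            levels[["vigorous"]] >= cp$moderate_upper)
  structure(list(
    n_days = n_days, sampling_rate = sampling_rate,
    sleep_h_mean = sleep_h_mean, sleep_h_sd = sleep_h_sd,
    sleep_onset_h = sleep_onset_h, sleep_onset_sd = sleep_onset_sd,
    levels = levels, slpa_dwell_min = slpa_dwell_min,
    mvpa_dwell_min = mvpa_dwell_min, sed_dwell_min = sed_dwell_min,
    light_dwell_min = light_dwell_min, mod_dwell_min = mod_dwell_min,
    vig_dwell_min = vig_dwell_min, nonwear_prob_day = nonwear_prob_day,
    nonwear_dur_min = nonwear_dur_min, temp_worn = temp_worn,
    temp_ambient = temp_ambient, temp_tau_min = temp_tau_min,
    scale_range = scale_range, offset_range = offset_range,
    noise_sd = noise_sd, posture_change_min = posture_change_min),
    class = "cohort_profile")
}

#' Preset: healthy younger-adult profile
#'
#' Short sedentary/light dwells and frequent moderate-to-vigorous bouts,
#' chosen so that pipeline endpoints land near published healthy
#' younger-adult group summaries (SLPA transition probability around
#' 0.04-0.05/min, MVPA time around 90 min/day, intensity gradient around
#' -2.3).
#' @param ... overrides passed to \code{\link{cohort_profile}}.
#' @return A \code{cohort_profile}.
#' @export
profile_younger <- function(...) {
  cohort_profile(slpa_dwell_min = 22, mvpa_dwell_min = 2.4,
                 mod_dwell_min = 2, vig_dwell_min = 0.12, ...)
}

#' Preset: healthy older-adult profile
#'
#' Longer sedentary/light bouts and reduced moderate-to-vigorous dwell:
#' SLPA transition probability around 0.02-0.03/min, MVPA time around
#' 45 min/day, more negative intensity gradient than the younger preset.
#' @param ... overrides passed to \code{\link{cohort_profile}}.
#' @return A \code{cohort_profile}.
#' @export
profile_older <- function(...) {
  cohort_profile(slpa_dwell_min = 40, mvpa_dwell_min = 1.9,
                 levels = c(sedentary = 0.02, light = 0.075,
                            moderate = 0.16, vigorous = 0.50),
                 mod_dwell_min = 1.8, vig_dwell_min = 0.09, ...)
}

# exponential dwell, floored to one 5 s epoch and rounded to the epoch grid
.rdwell_ep <- function(mean_min) {
  max(1L, as.integer(min(round(stats::rexp(1, 1 / (mean_min * 60)) / 5),
                         2^30)))
}

# random unit vector
.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic multi-day wrist recording with ground truth
#'
#' Simulates the full measurement chain on a 5 s state grid: nightly sleep
#' blocks (near-still wrist with occasional posture changes, worn
#' temperature), daytime semi-Markov alternation over the four activity
#' states with state-specific mean ENMO, optional doffed blocks (frozen
#' acceleration, exponential temperature decay toward ambient), slow
#' random-walk gravity orientation whose step size scales with activity
#' state, additive per-axis noise, and finally a per-axis scale/offset
#' miscalibration. All randomness derives from \code{seed}.
#'
#' @param profile a \code{\link{cohort_profile}}.
#' @param seed integer seed; fixed seed gives identical output.
#' @return List with \code{recording} (a \code{\link{raw_recording}} with
#'   temperature) and \code{truth}: \code{wear} and \code{sleep}
#'   \code{\link{interval_set}}s, \code{states} (data frame start/stop/state
#'   on the epoch grid), \code{calibration} (the corrective
#'   \code{calibration_model} that maps the recording back to truth), and
#'   \code{profile}.
#' @export
generate_recording <- function(profile, seed) {
  set.seed(seed)
  p <- profile
  ep_s <- 5
  total_s <- p$n_days * 86400
  nep <- total_s %/% ep_s
  state <- integer(nep)            # 0 sleep, 1 sed, 2 light, 3 mod, 4 vig
  # --- sleep intervals -------------------------------------------------
  sl_start <- sl_stop <- numeric(0)
  # morning tail of the previous night
  first_end <- max(3600, stats::rnorm(1, (p$sleep_onset_h + p$sleep_h_mean -
                                            24) * 3600, p$sleep_h_sd * 3600))
  sl_start <- 0; sl_stop <- min(first_end, total_s)
  for (d in seq_len(p$n_days)) {
    onset <- (d - 1) * 86400 +
      stats::rnorm(1, p$sleep_onset_h * 3600, p$sleep_onset_sd * 3600)
    dur <- stats::rnorm(1, p$sleep_h_mean * 3600, p$sleep_h_sd * 3600)
    if (onset >= total_s) break
    sl_start <- c(sl_start, onset); sl_stop <- c(sl_stop, min(onset + dur,
                                                              total_s))
  }
  sl_ep_start <- pmax(0L, as.integer(round(sl_start / ep_s)))
  sl_ep_stop <- pmin(nep, as.integer(round(sl_stop / ep_s)))
  for (i in seq_along(sl_ep_start))
    if (sl_ep_stop[i] > sl_ep_start[i])
      state[(sl_ep_start[i] + 1L):sl_ep_stop[i]] <- 0L
  asleep <- logical(nep)
  for (i in seq_along(sl_ep_start))
    if (sl_ep_stop[i] > sl_ep_start[i])
      asleep[(sl_ep_start[i] + 1L):sl_ep_stop[i]] <- TRUE

  # --- wake semi-Markov over SLPA/MVPA super-states --------------------
  wake_runs <- rle(!asleep)
  pos <- cumsum(c(0L, wake_runs$lengths))
  sub_dwell <- c(p$sed_dwell_min, p$light_dwell_min, p$mod_dwell_min,
                 p$vig_dwell_min)
  for (r in seq_along(wake_runs$lengths)) {
    if (!wake_runs$values[r]) next
    i0 <- pos[r] + 1L; i1 <- pos[r + 1L]
    i <- i0
    super <- 1L                     # start in SLPA
    while (i <= i1) {
      dw <- .rdwell_ep(if (super == 1L) p$slpa_dwell_min else p$mvpa_dwell_min)
      j1 <- min(i + dw - 1L, i1)
      # fill the super-bout with alternating sub-states
      sub <- if (super == 1L) 1L else 3L
      k <- i
      while (k <= j1) {
        sdw <- .rdwell_ep(sub_dwell[sub])
        k2 <- min(k + sdw - 1L, j1)
        state[k:k2] <- sub
        sub <- if (super == 1L) 3L - sub else 7L - sub  # 1<->2 or 3<->4
        k <- k2 + 1L
      }
      super <- 3L - super
      i <- j1 + 1L
    }
  }

  # --- non-wear blocks (daytime only) ----------------------------------
  nonwear <- logical(nep)
  nw_start <- nw_stop <- numeric(0)
  for (d in seq_len(p$n_days)) {
    if (stats::runif(1) > p$nonwear_prob_day) next
    dur_min <- min(max(stats::rexp(1, 1 / p$nonwear_dur_min), 30), 240)
    day_ep <- ((d - 1) * 86400 %/% ep_s + 1L):min(d * 86400 %/% ep_s, nep)
    wake_ep <- day_ep[!asleep[day_ep]]
    need <- as.integer(round(dur_min * 60 / ep_s))
    if (length(wake_ep) < need + 2L) next
    # pick a contiguous wake stretch that fits
    ok_starts <- wake_ep[seq_len(length(wake_ep) - need)]
    ok_starts <- ok_starts[!asleep[pmin(ok_starts + need, nep)]]
    if (!length(ok_starts)) next
    s0 <- sample(ok_starts, 1)
    nonwear[s0:(s0 + need - 1L)] <- TRUE
    nw_start <- c(nw_start, (s0 - 1L) * ep_s)
    nw_stop <- c(nw_stop, (s0 + need - 1L) * ep_s)
  }

  # --- orientation random walk on the sphere ---------------------------
  step_sd <- c(0.01, 0.3, 0.5, 0.8, 1.0)  # sleep, sed, light, mod, vig
  Dm <- matrix(0, 3, nep)
  d_cur <- .runit()
  next_posture <- stats::rexp(1, 1 / (p$posture_change_min * 60 / ep_s))
  zs <- matrix(stats::rnorm(3 * nep), 3, nep)
  for (e in seq_len(nep)) {
    if (nonwear[e]) { Dm[, e] <- d_cur; next }   # frozen while doffed
    s <- state[e]
    if (s == 0L) {
      next_posture <- next_posture - 1
      if (next_posture <= 0) {
        d_cur <- .runit()
        next_posture <- stats::rexp(1, 1 / (p$posture_change_min * 60 / ep_s))
      }
    }
    d_cur <- d_cur + step_sd[s + 1L] * zs[, e]
    d_cur <- d_cur / sqrt(sum(d_cur^2))
    Dm[, e] <- d_cur
  }

  # --- temperature on the epoch grid -----------------------------------
  temp_ep <- numeric(nep)
  t_cur <- p$temp_worn
  tau_ep <- p$temp_tau_min * 60 / ep_s
  tau_warm_ep <- (p$temp_tau_min / 2) * 60 / ep_s
  for (e in seq_len(nep)) {
    target <- if (nonwear[e]) p$temp_ambient else p$temp_worn
    tau <- if (nonwear[e]) tau_ep else tau_warm_ep
    t_cur <- target + (t_cur - target) * exp(-1 / tau)
    temp_ep[e] <- t_cur
  }

  # --- expand to samples ------------------------------------------------
  fs <- p$sampling_rate
  spw <- as.integer(round(ep_s * fs))
  n <- nep * spw
  idx <- rep(seq_len(nep), each = spw)
  lv <- c(0.005, unname(p$levels))           # sleep level first
  Lep <- lv[state + 1L]
  Lep[nonwear] <- 0
  amp <- 1 + Lep[idx]
  acc <- t(Dm)[idx, , drop = FALSE] * amp
  if (p$noise_sd > 0) {
    noise <- matrix(stats::rnorm(3 * n, 0, p$noise_sd), n, 3)
    noise[nonwear[idx], ] <- 0               # doffed device is frozen
    acc <- acc + noise
  }
  temp <- temp_ep[idx] + stats::rnorm(n, 0, 0.02)

  # --- plant miscalibration --------------------------------------------
  cal_scale <- stats::runif(3, p$scale_range[1], p$scale_range[2])
  cal_offset <- stats::runif(3, p$offset_range[1], p$offset_range[2])
  # corrective model: a_true = scale * a_obs + offset
  acc_obs <- sweep(sweep(acc, 2, cal_offset, "-"), 2, cal_scale, "/")

  time <- (seq_len(n) - 1) / fs
  rec <- raw_recording(time, acc_obs, temperature = temp,
                       sampling_rate = fs)
  truth_cal <- structure(list(scale = cal_scale, offset = cal_offset,
                              n_rest_windows = NA_integer_, converged = TRUE,
                              residual = 0),
                         class = "calibration_model")
  wear_iv <- if (length(nw_start))
    .complement_wear(interval_set(nw_start, nw_stop,
                                  rep("nonwear", length(nw_start))),
                     0, total_s)
  else interval_set(0, total_s, "wear")
  sleep_iv <- interval_set(sl_ep_start * ep_s, sl_ep_stop * ep_s,
                           rep("sleep", length(sl_ep_start)))
  st_r <- rle(ifelse(nonwear, 5L, state))
  st_end <- cumsum(st_r$lengths)
  st_lab <- c("sleep", "sedentary", "light", "moderate", "vigorous",
              "nonwear")[st_r$values + 1L]
  states <- data.frame(start = (st_end - st_r$lengths) * ep_s,
                       stop = st_end * ep_s, state = st_lab,
                       stringsAsFactors = FALSE)
  list(recording = rec,
       truth = list(wear = wear_iv, sleep = sleep_iv, states = states,
                    calibration = truth_cal, profile = p))
}

#' Generate a still-orientation recording for calibration testing
#'
#' A recording consisting purely of rest blocks: the device sits in a
#' sequence of random orientations with small noise, optionally
#' miscalibrated. This is the controlled input for calibration
#' parameter-recovery checks, providing guaranteed sphere coverage.
#'
#' @param seed integer seed.
#' @param n_orient number of distinct orientations (default 72).
#' @param orient_dur_s seconds per orientation (default 600, i.e. 12 h
#'   total at the defaults).
#' @param sampling_rate Hz (default 10).
#' @param noise_sd per-axis noise SD in g.
#' @param scale,offset corrective 3-vectors planted in the recording
#'   (the observed signal is \code{(a - offset) / scale}).
#' @return List with \code{recording} and \code{truth} (the corrective
#'   \code{calibration_model}).
#' @export
generate_still_recording <- function(seed, n_orient = 72,
                                     orient_dur_s = 600,
                                     sampling_rate = 10, noise_sd = 0.003,
                                     scale = c(1, 1, 1),
                                     offset = c(0, 0, 0)) {
  set.seed(seed)
  per <- as.integer(orient_dur_s * sampling_rate)
  n <- n_orient * per
  dirs <- t(vapply(seq_len(n_orient), function(i) .runit(), numeric(3)))
  acc <- dirs[rep(seq_len(n_orient), each = per), , drop = FALSE] +
    matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  acc_obs <- sweep(sweep(acc, 2, offset, "-"), 2, scale, "/")
  rec <- raw_recording((seq_len(n) - 1) / sampling_rate, acc_obs,
                       sampling_rate = sampling_rate)
  truth <- structure(list(scale = scale, offset = offset,
                          n_rest_windows = n_orient, converged = TRUE,
                          residual = 0),
                     class = "calibration_model")
  list(recording = rec, truth = truth)
}

#' Generate a two-group synthetic cohort
#'
#' Draws \code{n_per_group} subjects per group with ages uniform in the
#' group ranges and per-subject lognormal jitter on the profile dwell
#' times, generates each subject's recording, and returns the recordings
#' with a subject metadata table. Deterministic under \code{seed}.
#'
#' @param profile_a,profile_b group \code{\link{cohort_profile}}s (e.g.
#'   \code{\link{profile_younger}} and \code{\link{profile_older}}).
#' @param n_per_group subjects per group (at least 2).
#' @param age_range_a,age_range_b age ranges in years.
#' @param seed integer seed.
#' @param jitter_sd SD of the lognormal dwell-time jitter (default 0.25).
#' @return List with \code{subjects} (list of \code{generate_recording}
#'   outputs, names matching metadata) and \code{meta} (data frame:
#'   \code{subject}, \code{age}, \code{group}).
#' @export
make_cohort <- function(profile_a = profile_younger(),
                        profile_b = profile_older(), n_per_group = 10,
                        age_range_a = c(23, 39), age_range_b = c(65, 85),
                        seed = 1, jitter_sd = 0.25) {
  stopifnot(n_per_group >= 2L)
  set.seed(seed)
  n_tot <- 2L * n_per_group
  ages <- c(stats::runif(n_per_group, age_range_a[1], age_range_a[2]),
            stats::runif(n_per_group, age_range_b[1], age_range_b[2]))
  groups <- rep(c("A", "B"), each = n_per_group)
  sub_seeds <- sample.int(2^31 - 1, n_tot)
  jit <- matrix(stats::rnorm(2L * n_tot, 0, jitter_sd), n_tot, 2)
  subjects <- vector("list", n_tot)
  ids <- sprintf("S%02d", seq_len(n_tot))
  for (i in seq_len(n_tot)) {
    p <- if (groups[i] == "A") profile_a else profile_b
    p$slpa_dwell_min <- p$slpa_dwell_min * exp(jit[i, 1])
    p$mvpa_dwell_min <- p$mvpa_dwell_min * exp(jit[i, 2])
    subjects[[i]] <- generate_recording(p, sub_seeds[i])
  }
  names(subjects) <- ids
  list(subjects = subjects,
       meta = data.frame(subject = ids, age = ages, group = groups,
                         stringsAsFactors = FALSE))
}
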