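#' Extract SLPA/MVPA bouts from an epoch series
#'
#' Binarizes the epoch series at the MVPA boundary (0.110 g): maximal runs
#' of same-state epochs become bouts, with durations in minutes. The first
#' and last run of each contiguous segment touch a period or non-wear
#' boundary, so their true length is unknown (right/left censored); they
#' are flagged and, by default, dropped from the duration-distribution
#' metrics while still counting toward transition probability.
#'
#' @param epochs an \code{\link{epoch_series}}.
#' @param cuts a \code{\link{cut_points}}; the split is at
#'   \code{light_upper}. Set the boundary to \code{sedentary_upper} via a
#'   custom \code{cut_points} for the classic sedentary-vs-active variant.
#' @param boundary \code{"mvpa"} (default, 0.110 g) or \code{"sedentary"}
#'   (0.050 g) state split.
#' @return List with two elements \code{SLPA} and \code{MVPA}, each of
#'   class \code{bout_list}: \code{durations} (minutes), \code{censored}
#'   (logical, same length), \code{state}.
#' @export
extract_bouts <- function(epochs, cuts = cut_points(),
                          boundary = c("mvpa", "sedentary")) {
  boundary <- match.arg(boundary)
  thr <- if (boundary == "mvpa") cuts$light_upper else cuts$sedentary_upper
  active <- epochs$values >= thr
  n <- length(active)
  if (!n) {
    empty <- function(s) structure(list(state = s, durations = numeric(0),
                                        censored = logical(0)),
                                   class = "bout_list")
    return(list(SLPA = empty("SLPA"), MVPA = empty("MVPA")))
  }
  # segment breaks where epochs are not contiguous in time
  gaps <- which(diff(epochs$epoch_start) > 1.5 * epochs$epoch_length)
  seg_id <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% gaps)))
  dur_a <- dur_s <- numeric(0)
  cen_a <- cen_s <- logical(0)
  for (s in unique(seg_id)) {
    a <- active[seg_id == s]
    r <- rle(a)
    k <- length(r$lengths)
    cens <- seq_len(k) %in% c(1L, k)   # runs abutting segment boundaries
    mins <- r$lengths * epochs$epoch_length / 60
    dur_a <- c(dur_a, mins[r$values]); cen_a <- c(cen_a, cens[r$values])
    dur_s <- c(dur_s, mins[!r$values]); cen_s <- c(cen_s, cens[!r$values])
  }
  list(SLPA = structure(list(state = "SLPA", durations = dur_s,
                             censored = cen_s), class = "bout_list"),
       MVPA = structure(list(state = "MVPA", durations = dur_a,
                             censored = cen_a), class = "bout_list"))
}

# durations used for distribution-shape metrics (censored dropped unless
# nothing would remain)
.frag_durations <- function(bouts, drop_censored = TRUE) {
  d <- bouts$durations
  if (drop_censored && any(!bouts$censored)) d <- d[!bouts$censored]
  d
}

#' Transition probability out of a state, per minute
#'
#' Number of bouts divided by the total minutes spent in the state: the
#' reciprocal of the mean bout duration. Higher values mean the state is
#' broken up more often (more fragmented accumulation).
#'
#' @param bouts a \code{bout_list} from \code{\link{extract_bouts}}.
#' @return Per-minute transition probability, or \code{NA} when there are
#'   no bouts.
#' @export
transition_probability <- function(bouts) {
  d <- bouts$durations
  if (!length(d)) return(NA_real_)
  length(d) / sum(d)
}

#' Average bout duration, in minutes
#' @param bouts a \code{bout_list}.
#' @return Mean bout duration (minutes), the reciprocal of
#'   \code{\link{transition_probability}}; \code{NA} when empty.
#' @export
average_duration <- function(bouts) {
  d <- bouts$durations
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Gini index of the bout-duration distribution
#'
#' \eqn{G = \sum_i \sum_j |d_i - d_j| / (2 n \sum_k d_k)}: 0 when all bouts
#' are equally long, approaching 1 when total time is dominated by one long
#' bout. Invariant to uniform rescaling of durations.
#'
#' @param bouts a \code{bout_list}.
#' @param drop_censored exclude boundary-censored bouts (default TRUE).
#' @return Gini index in [0, 1], or \code{NA} when empty.
#' @export
gini_index <- function(bouts, drop_censored = TRUE) {
  d <- .frag_durations(bouts, drop_censored)
  n <- length(d)
  if (!n) return(NA_real_)
  if (n == 1L) return(0)
  ds <- sort(d)
  # sum_i sum_j |di - dj| = 2 * sum_i (2i - n - 1) * d_(i)
  tot <- 2 * sum((2 * seq_len(n) - n - 1) * ds)
  tot / (2 * n * sum(ds))
}

#' Average hazard of bout termination
#'
#' Mean, over the distinct observed durations t, of the empirical hazard
#' \eqn{h(t) = n(t) / n(\ge t)} where \eqn{n(t)} is the number of bouts
#' ending at exactly t. Higher values mean bouts tend to end early.
#'
#' @inheritParams gini_index
#' @return Dimensionless mean hazard, or \code{NA} when empty.
#' @export
average_hazard <- function(bouts, drop_censored = TRUE) {
  d <- .frag_durations(bouts, drop_censored)
  if (!length(d)) return(NA_real_)
  tab <- table(d)
  n_at <- as.numeric(tab)
  n_risk <- rev(cumsum(rev(n_at)))     # bouts with duration >= t
  mean(n_at / n_risk)
}

#' Power-law exponent of the bout-duration distribution
#'
#' Continuous maximum-likelihood estimate
#' \eqn{\alpha = 1 + n / \sum_i \ln(d_i / d_{min})} with \eqn{d_{min}} the
#' smallest observed duration. Larger alpha means long bouts are rarer.
#'
#' @inheritParams gini_index
#' @return Alpha (> 1), or \code{NA} when all durations are equal (the
#'   estimate diverges) or fewer than 2 bouts remain.
#' @export
powerlaw_alpha <- function(bouts, drop_censored = TRUE) {
  d <- .frag_durations(bouts, drop_censored)
  if (length(d) < 2L || any(d <= 0)) return(NA_real_)
  s <- sum(log(d / min(d)))
  if (s == 0) return(NA_real_)
  1 + length(d) / s
}

#' All fragmentation metrics for one epoch series
#'
#' @param epochs an \code{\link{epoch_series}} (wake period).
#' @param cuts a \code{\link{cut_points}}.
#' @param drop_censored exclude boundary-censored bouts from Gini, hazard
#'   and alpha (they always count toward transition probability and average
#'   duration).
#' @return Named numeric vector: \code{slpa_trans_prob},
#'   \code{mvpa_trans_prob}, \code{slpa_avg_dur}, \code{mvpa_avg_dur},
#'   \code{slpa_gini}, \code{mvpa_gini}, \code{slpa_hazard},
#'   \code{mvpa_hazard}, \code{slpa_alpha}, \code{mvpa_alpha}.
#' @export
fragmentation_metrics <- function(epochs, cuts = cut_points(),
                                  drop_censored = TRUE) {
  b <- extract_bouts(epochs, cuts)
  c(slpa_trans_prob = transition_probability(b$SLPA),
    mvpa_trans_prob = transition_probability(b$MVPA),
    slpa_avg_dur = average_duration(b$SLPA),
    mvpa_avg_dur = average_duration(b$MVPA),
    slpa_gini = gini_index(b$SLPA, drop_censored),
    mvpa_gini = gini_index(b$MVPA, drop_censored),
    slpa_hazard = average_hazard(b$SLPA, drop_censored),
    mvpa_hazard = average_hazard(b$MVPA, drop_censored),
    slpa_alpha = powerlaw_alpha(b$SLPA, drop_censored),
    mvpa_alpha = powerlaw_alpha(b$MVPA, drop_censored))
}
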