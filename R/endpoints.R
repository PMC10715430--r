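#' ENMO cut-points for activity levels
#'
#' Half-open intensity brackets on the ENMO epoch value: sedentary
#' [0, 0.050) g, light [0.050, 0.110) g, moderate [0.110, 0.440) g,
#' vigorous [0.440, Inf) g. MVPA is everything at or above 0.110 g; SLPA
#' everything below it.
#'
#' @param sedentary_upper,light_upper,moderate_upper upper bracket bounds
#'   in g.
#' @return A list of class \code{cut_points}.
#' @export
cut_points <- function(sedentary_upper = 0.050, light_upper = 0.110,
                       moderate_upper = 0.440) {
  stopifnot(0 < sedentary_upper, sedentary_upper < light_upper,
            light_upper < moderate_upper)
  structure(list(sedentary_upper = sedentary_upper,
                 light_upper = light_upper,
                 moderate_upper = moderate_upper),
            class = "cut_points")
}

#' Classify epochs into activity levels
#' @param epochs an \code{\link{epoch_series}}.
#' @param cuts a \code{\link{cut_points}}.
#' @return Integer vector (1 = sedentary, 2 = light, 3 = moderate,
#'   4 = vigorous), half-open bracket convention: a value exactly on a
#'   boundary belongs to the level above it.
#' @export
classify_epochs <- function(epochs, cuts = cut_points()) {
  findInterval(epochs$values,
               c(cuts$sedentary_upper, cuts$light_upper,
                 cuts$moderate_upper)) + 1L
}

#' Time in activity levels, in minutes
#'
#' Each epoch is assigned to exactly one bracket; minutes are epoch counts
#' times the epoch length. The four levels always sum to the total epoch
#' time; MVPA = moderate + vigorous, SLPA = sedentary + light.
#'
#' @param epochs an \code{\link{epoch_series}}.
#' @param cuts a \code{\link{cut_points}}.
#' @return Named numeric vector with elements \code{sedentary},
#'   \code{light}, \code{moderate}, \code{vigorous}, \code{MVPA},
#'   \code{SLPA} (minutes).
#' @export
time_in_levels <- function(epochs, cuts = cut_points()) {
  lev <- classify_epochs(epochs, cuts)
  mins <- tabulate(lev, 4L) * epochs$epoch_length / 60
  c(sedentary = mins[1], light = mins[2], moderate = mins[3],
    vigorous = mins[4], MVPA = mins[3] + mins[4], SLPA = mins[1] + mins[2])
}

#' Time accumulated in bouts of a level, in minutes
#'
#' A qualifying bout is a contiguous epoch window of at least
#' \code{bout_min} minutes that starts and ends with in-level epochs and in
#' which at least \code{criterion} of the epochs are in-level (default
#' 80\%). The returned value is the total time covered by the union of all
#' qualifying windows, so interruptions shorter than the tolerance are
#' counted inside a bout.
#'
#' @param epochs an \code{\link{epoch_series}}.
#' @param level \code{"MVPA"} or \code{"SLPA"}.
#' @param bout_min minimum bout length in minutes.
#' @param criterion minimum in-level fraction within a bout.
#' @param cuts a \code{\link{cut_points}}.
#' @return Bouted time in minutes.
#' @export
time_in_bouts <- function(epochs, level = c("MVPA", "SLPA"), bout_min = 10,
                          criterion = 0.8, cuts = cut_points()) {
  level <- match.arg(level)
  stopifnot(bout_min >= 1)
  inlev <- if (level == "MVPA") epochs$values >= cuts$light_upper
           else epochs$values < cuts$light_upper
  n <- length(inlev)
  min_ep <- as.integer(ceiling(bout_min * 60 / epochs$epoch_length))
  if (!any(inlev) || n < min_ep) return(0)
  covered <- .bout_cover(inlev, min_ep, criterion)
  sum(covered) * epochs$epoch_length / 60
}

# logical cover of the union of all qualifying bout windows.
# window [i, j] qualifies iff inlev[i], inlev[j], j - i + 1 >= min_ep and
# sum(inlev[i:j]) >= criterion * (j - i + 1). Using T(k) = S(k) - crit * k
# (S = prefix sum), the fraction condition is T(j) >= T(i - 1); for each
# in-level i the union contribution is [i, jmax(i)] with jmax the largest
# in-level j satisfying it, found by binary search on the suffix maximum of
# T over in-level positions.
.bout_cover <- function(inlev, min_ep, criterion) {
  n <- length(inlev)
  S <- cumsum(inlev)
  T_ <- S - criterion * seq_len(n)
  P <- which(inlev)
  m <- length(P)
  TP <- T_[P]
  M <- rev(cummax(rev(TP)))               # suffix max, non-increasing
  negM <- -M                              # non-decreasing
  eps <- 1e-9
  diffmark <- integer(n + 1L)
  T0 <- c(0, T_)                          # T(i-1) with T(0) = 0
  for (idx in seq_len(m)) {
    i <- P[idx]
    cmin <- T0[i] - eps
    kstar <- findInterval(-cmin, negM)
    if (kstar < 1L) next
    j <- P[kstar]
    if (j >= i + min_ep - 1L) {
      diffmark[i] <- diffmark[i] + 1L
      diffmark[j + 1L] <- diffmark[j + 1L] - 1L
    }
  }
  cumsum(diffmark[seq_len(n)]) > 0L
}

#' Maximum rolling-window acceleration, in g
#'
#' Maximum over epoch-stride rolling means of the ENMO epoch series across
#' windows of \code{window_min} minutes (e.g. the "maximum 6 min
#' acceleration" endpoint).
#'
#' @param epochs an \code{\link{epoch_series}}.
#' @param window_min window length in minutes.
#' @return Maximum windowed mean ENMO in g, or \code{NA} when the period is
#'   shorter than the window.
#' @export
max_windowed_acc <- function(epochs, window_min) {
  m <- as.integer(round(window_min * 60 / epochs$epoch_length))
  v <- epochs$values
  if (length(v) < m || m < 1L) return(NA_real_)
  cs <- cumsum(c(0, v))
  max((cs[(m + 1L):(length(v) + 1L)] - cs[seq_len(length(v) - m + 1L)]) / m)
}

#' Intensity gradient
#'
#' A threshold-free activity descriptor: epoch time is histogrammed into
#' evenly spaced ENMO bins of width \code{bin_width} (0.025 g) starting at
#' 0; empty bins are dropped; and ordinary least squares of the natural log
#' of time in each bin (minutes) on the natural log of the bin midpoint (g)
#' yields the gradient (slope), the intercept and the Pearson r of the fit.
#' More negative gradients indicate activity time concentrated at low
#' intensities.
#'
#' @param epochs an \code{\link{epoch_series}}.
#' @param bin_width bin width in g (default 0.025).
#' @return A list of class \code{ig_result}: \code{gradient},
#'   \code{intercept}, \code{r_value}, \code{bin_width}, \code{bins_used}.
#' @export
intensity_gradient <- function(epochs, bin_width = 0.025) {
  v <- epochs$values
  bin <- floor(v / bin_width)
  tab <- table(bin)
  mids <- (as.numeric(names(tab)) + 0.5) * bin_width
  mins <- as.numeric(tab) * epochs$epoch_length / 60
  keep <- mins > 0
  mids <- mids[keep]; mins <- mins[keep]
  if (length(mids) < 2L)
    stop("intensity gradient undefined: fewer than 2 non-empty bins",
         call. = FALSE)
  lx <- log(mids); ly <- log(mins)
  fit <- stats::lm(ly ~ lx)
  structure(list(gradient = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_value = stats::cor(lx, ly),
                 bin_width = bin_width, bins_used = length(mids)),
            class = "ig_result")
}

#' Daily endpoint battery for one wake-period epoch series
#'
#' Computes the full set of per-period activity endpoints: time in the four
#' levels plus MVPA/SLPA, bouted MVPA time for several bout lengths,
#' maximum 6 and 15 min accelerations, the intensity gradient triple and
#' mean ENMO.
#'
#' @param epochs an \code{\link{epoch_series}} (typically a wake period).
#' @param cuts a \code{\link{cut_points}}.
#' @param bout_lengths bout lengths in minutes (default 1, 5, 10).
#' @param max_windows rolling-maximum window lengths in minutes
#'   (default 6, 15).
#' @return Named numeric vector of endpoint values; undefined endpoints
#'   (e.g. IG with a degenerate histogram) are \code{NA}.
#' @export
compute_endpoints <- function(epochs, cuts = cut_points(),
                              bout_lengths = c(1, 5, 10),
                              max_windows = c(6, 15)) {
  out <- time_in_levels(epochs, cuts)
  for (b in bout_lengths)
    out[sprintf("MVPA_bout_%dmin", b)] <-
      time_in_bouts(epochs, "MVPA", b, cuts = cuts)
  for (w in max_windows)
    out[sprintf("max_acc_%dmin", w)] <- max_windowed_acc(epochs, w)
  ig <- tryCatch(intensity_gradient(epochs), error = function(e) NULL)
  out["IG"] <- if (is.null(ig)) NA_real_ else ig$gradient
  out["IG_intercept"] <- if (is.null(ig)) NA_real_ else ig$intercept
  out["IG_r"] <- if (is.null(ig)) NA_real_ else ig$r_value
  out["mean_ENMO"] <- mean(epochs$values)
  out
}
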