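#' Find rest windows for autocalibration
#'
#' Splits the recording into non-overlapping windows and keeps those whose
#' per-axis standard deviation is below \code{sd_thresh} on all three axes:
#' samples that can reasonably be assumed to be at rest, where the measured
#' vector should be pure gravity (norm 1 g).
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param win_s window length in seconds (default 10).
#' @param sd_thresh per-axis standard-deviation threshold in g
#'   (default 0.013).
#' @return Matrix with one row per rest window and columns x, y, z: the
#'   window mean acceleration. May have zero rows.
#' @export
find_rest_windows <- function(rec, win_s = 10, sd_thresh = 0.013) {
  wlen <- as.integer(round(win_s * rec$sampling_rate))
  n <- nrow(rec$acc)
  if (wlen < 2L || n < wlen)
    stop("recording shorter than one rest window", call. = FALSE)
  nwin <- n %/% wlen
  keep <- n - n %% wlen
  means <- sds <- matrix(0, nwin, 3)
  for (j in 1:3) {
    m <- matrix(rec$acc[seq_len(keep), j], nrow = wlen)
    means[, j] <- colMeans(m)
    sds[, j] <- sqrt(colMeans(m^2) - colMeans(m)^2) * sqrt(wlen / (wlen - 1))
  }
  still <- rowSums(sds < sd_thresh) == 3L
  colnames(means) <- c("x", "y", "z")
  means[still, , drop = FALSE]
}

#' Fit a unit-sphere calibration model
#'
#' Estimates a per-axis gain and offset mapping rest-window accelerations
#' onto the unit sphere, by iteratively re-weighted least squares: at each
#' iteration the currently calibrated points are projected radially onto the
#' sphere and each axis is regressed onto its projection, which has a
#' closed-form per-axis update. The procedure minimises
#' \eqn{\sum (\lVert s \circ a + b\rVert - 1)^2}.
#'
#' @param rest_points matrix of rest-window mean 3-vectors (g), e.g. from
#'   \code{\link{find_rest_windows}}.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   maximum parameter change.
#' @param scale_bounds accepted range for fitted gains; a fit outside is
#'   rejected (identity model, \code{converged = FALSE}).
#' @return An object of class \code{calibration_model}: list with
#'   \code{scale} (3-vector), \code{offset} (3-vector, g),
#'   \code{n_rest_windows}, \code{converged}, and \code{residual} (mean
#'   absolute deviation of the calibrated norms from 1, in g).
#' @details Sphere coverage is required: every axis must contribute rest
#'   points of both signs, otherwise the gain on that axis is not
#'   identifiable and the identity model is returned with
#'   \code{converged = FALSE}. Fewer than 9 rest points is an error.
#' @export
fit_calibration <- function(rest_points, max_iter = 1000, tol = 1e-7,
                            scale_bounds = c(0.8, 1.2)) {
  pts <- as.matrix(rest_points)
  if (nrow(pts) < 9L)
    stop("insufficient rest data: need at least 9 rest points", call. = FALSE)
  identity_model <- function(conv) {
    structure(list(scale = c(1, 1, 1), offset = c(0, 0, 0),
                   n_rest_windows = nrow(pts), converged = conv,
                   residual = mean(abs(sqrt(rowSums(pts^2)) - 1))),
              class = "calibration_model")
  }
  # identifiability: need both orientations on each axis
  coverage <- vapply(1:3, function(j)
    any(pts[, j] > 0.3) && any(pts[, j] < -0.3), logical(1))
  if (!all(coverage)) return(identity_model(FALSE))

  scale <- c(1, 1, 1); offset <- c(0, 0, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- sweep(sweep(pts, 2, scale, "*"), 2, offset, "+")
    nrm <- sqrt(rowSums(cur^2))
    target <- cur / nrm                       # radial projection onto sphere
    w <- rep(1, nrow(cur))
    new_scale <- scale; new_offset <- offset
    for (j in 1:3) {
      # weighted simple regression target_j = a * cur_j + c
      x <- cur[, j]; y <- target[, j]
      sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
      vxx <- sum(w * (x - mx)^2)
      a <- sum(w * (x - mx) * (y - my)) / vxx
      cc <- my - a * mx
      new_scale[j] <- scale[j] * a
      new_offset[j] <- offset[j] * a + cc
    }
    delta <- max(abs(c(new_scale - scale, new_offset - offset)))
    scale <- new_scale; offset <- new_offset
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged ||
      any(scale <= scale_bounds[1]) || any(scale >= scale_bounds[2]))
    return(identity_model(FALSE))
  cal <- sweep(sweep(pts, 2, scale, "*"), 2, offset, "+")
  res_after <- mean(abs(sqrt(rowSums(cal^2)) - 1))
  res_before <- mean(abs(sqrt(rowSums(pts^2)) - 1))
  if (res_after > res_before + 1e-9) return(identity_model(FALSE))
  structure(list(scale = scale, offset = offset,
                 n_rest_windows = nrow(pts), converged = TRUE,
                 residual = res_after),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> scale (%.4f, %.4f, %.4f), offset (%.4f, %.4f, %.4f) g\n  %d rest windows, residual %.5f g, converged: %s\n",
    x$scale[1], x$scale[2], x$scale[3],
    x$offset[1], x$offset[2], x$offset[3],
    x$n_rest_windows, x$residual, x$converged))
  invisible(x)
}

#' Apply a calibration model to a recording
#'
#' Elementwise \code{a' = s * a + b}; timestamps and temperature are
#' untouched.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param model a \code{calibration_model}.
#' @return A calibrated \code{\link{raw_recording}}.
#' @export
apply_calibration <- function(rec, model) {
  stopifnot(all(is.finite(model$scale)), all(is.finite(model$offset)))
  rec$acc <- sweep(sweep(rec$acc, 2, model$scale, "*"), 2, model$offset, "+")
  rec
}

#' Calibrate a recording end to end
#'
#' Convenience wrapper: find rest windows, fit, and apply. When the fit is
#' rejected (bad coverage or out-of-bounds gains) the recording is returned
#' unchanged together with the identity model.
#'
#' @inheritParams find_rest_windows
#' @param ... passed to \code{\link{fit_calibration}}.
#' @return List with fields \code{recording} and \code{model}.
#' @export
calibrate_recording <- function(rec, win_s = 10, sd_thresh = 0.013, ...) {
  rest <- find_rest_windows(rec, win_s = win_s, sd_thresh = sd_thresh)
  if (nrow(rest) < 9L) {
    model <- structure(list(scale = c(1, 1, 1), offset = c(0, 0, 0),
                            n_rest_windows = nrow(rest), converged = FALSE,
                            residual = NA_real_),
                       class = "calibration_model")
    return(list(recording = rec, model = model))
  }
  model <- fit_calibration(rest, ...)
  list(recording = apply_calibration(rec, model), model = model)
}

#' Serialize a calibration model to JSON
#' @param model a \code{calibration_model}.
#' @param path output path.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(list(scale = model$scale, offset = model$offset,
                            n_rest_windows = model$n_rest_windows,
                            converged = model$converged,
                            residual = model$residual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
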