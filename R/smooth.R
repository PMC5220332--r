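#' Resample a raw time course onto an equally spaced grid
#'
#' Prepares raw, possibly unequally spaced or replicated time courses for
#' delay analysis: fits a cubic smoothing spline to all (time, value) points
#' pooled across replicates and evaluates it on \code{n_points} equally
#' spaced times spanning the observed range (both endpoints included). The
#' smoothing parameter is chosen by generalized cross-validation unless
#' \code{spar} is given. With \code{smooth = FALSE} a cubic interpolation
#' spline is used instead; values already on an equal grid then pass through
#' unchanged.
#'
#' This is a generic stand-in for model-based trajectory summarisation
#' (e.g. mixed-effect model splines): downstream delay estimation only
#' requires a single value per time point on an equal grid.
#'
#' @param times numeric vector of observation times (unsorted and repeated
#'   times allowed; replicates share a time value).
#' @param values numeric vector of expression values, same length.
#' @param n_points number of equally spaced output time points (>= 4).
#' @param smooth logical; smoothing spline (default) or pure interpolation.
#' @param spar optional smoothing parameter passed to
#'   \code{\link[stats]{smooth.spline}}; by default chosen by GCV.
#' @return list with \code{times} (the equally spaced grid) and
#'   \code{values} (fitted expression at those times).
#' @examples
#' tc <- list(times = c(0, 1, 2, 4, 8, 16), values = 2 * c(0, 1, 2, 4, 8, 16))
#' resample_trajectory(tc$times, tc$values, n_points = 14)$values
#' @export
resample_trajectory <- function(times, values, n_points = 14L,
                                smooth = TRUE, spar = NULL) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  ok <- is.finite(times) & is.finite(values)
  if (!all(ok)) stop("non-finite entries in the time course")
  if (length(unique(times)) < 4L)
    stop("need at least 4 distinct time values, got ",
         length(unique(times)))
  if (n_points < 4L) stop("'n_points' must be at least 4")
  grid <- seq(min(times), max(times), length.out = n_points)
  if (smooth) {
    fit <- if (is.null(spar))
      stats::smooth.spline(times, values, cv = FALSE)  # GCV
    else
      stats::smooth.spline(times, values, spar = spar)
    vals <- stats::predict(fit, grid)$y
  } else {
    # interpolation through per-time means (replicates averaged)
    mv <- tapply(values, times, mean)
    tt <- as.numeric(names(mv))
    vals <- stats::spline(tt, as.numeric(mv), xout = grid,
                          method = "fmm")$y
  }
  list(times = grid, values = vals)
}

#' Remove a linear time trend from a trajectory
#'
#' Returns the residuals of an ordinary least-squares regression of the
#' expression values against the time index 1..T. Constant drifts over time
#' (rare in short biological time courses, but possible) otherwise dominate
#' the low-frequency Fourier components and distort delay estimates, so they
#' should be removed before analysis. The output has zero mean and zero
#' linear trend; applying \code{detrend} twice gives the same result as
#' applying it once.
#'
#' @param x numeric trajectory of length T >= 4.
#' @return detrended numeric vector of the same length.
#' @examples
#' detrend(3 + 2 * (1:10))          # all zero
#' @export
detrend <- function(x) {
  x <- as_trajectory(x)
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}
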