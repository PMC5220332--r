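#' Estimate the delay between a reference and a query trajectory
#'
#' Fits the delay model for one reference/query trajectory pair. Both
#' trajectories are decomposed with the discrete Fourier transform; the
#' dominant frequency K is identified from the reference's amplitude
#' spectrum; the phase-angle difference at K gives an initial integer delay
#' estimate, which is refined by maximising the absolute lagged Pearson
#' correlation over a small candidate lag set (see [refine_delay()]). The
#' refined delay realigns the trajectories and the signed correlation on the
#' realigned overlap measures the strength and direction of the association.
#'
#' A positive delay means the reference changes expression before the query;
#' a negative delay means the reference lags behind the query; zero means the
#' pair changes simultaneously. The correlation keeps its sign, so inhibitory
#' relationships (e.g. a miRNA suppressing its target mRNA) appear as large
#' negative correlations.
#'
#' @param x numeric vector: reference trajectory at T >= 4 equally spaced
#'   time points.
#' @param y numeric vector of the same length: query trajectory.
#' @param window half-width of the local lag search in the refinement stage.
#' @param K optional integer dominant frequency; by default estimated from
#'   the reference via [dominant_frequency()].
#' @return an object of class \code{"dynomics"}: a list with elements
#'   \code{K}, \code{delta_angle} (degrees, [0, 360)), \code{delta0},
#'   \code{delta_star}, \code{r_star}, \code{p_value} (two-sided, on the
#'   realigned overlap length), \code{n_overlap}, \code{T}, and the input
#'   trajectories \code{x}, \code{y}.
#' @examples
#' t <- 1:14
#' x <- cos(2 * pi * (t - 1) / 14)
#' y <- cos(2 * pi * (t - 1 - 2) / 14)   # query delayed by 2
#' fit <- dynomics(x, y)
#' fit
#' coef(fit)
#' @seealso [screen_associations()] for all-pairs screening,
#'   [align_trajectories()] for realignment.
#' @export
dynomics <- function(x, y, window = 1L, K = NULL) {
  x <- as_trajectory(x)
  y <- as_trajectory(y)
  if (length(x) != length(y))
    stop("reference and query must share the same number of time points")
  T <- length(x)

  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fit <- list(K = NA_integer_, delta_angle = NA_real_,
                delta0 = NA_integer_, delta_star = NA_integer_,
                r_star = NA_real_, p_value = NA_real_,
                n_overlap = NA_integer_, T = T, x = x, y = y,
                degenerate = TRUE, call = match.call())
    class(fit) <- "dynomics"
    return(fit)
  }

  cx <- dft_components(x)
  cy <- dft_components(y)
  if (is.null(K)) K <- dominant_frequency(cx)
  K <- as.integer(K)
  if (K < 1L || K > T - 1L) stop("'K' must lie in 1..T-1")

  delta <- angular_difference(cx$phase_deg[K], cy$phase_deg[K])
  delta0 <- initial_delay(delta, T, K)
  ref <- refine_delay(x, y, delta0, window = window)
  n <- T - abs(ref$delta_star)

  fit <- list(K = K, delta_angle = delta, delta0 = delta0,
              delta_star = ref$delta_star, r_star = ref$r_star,
              p_value = correlation_pvalue(ref$r_star, n),
              n_overlap = n, T = T, x = x, y = y,
              degenerate = FALSE, call = match.call())
  class(fit) <- "dynomics"
  fit
}

#' @export
print.dynomics <- function(x, digits = 4, ...) {
  cat("Delay estimate between time-course trajectories\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate pair (zero-variance trajectory); no estimate\n")
    return(invisible(x))
  }
  cat(sprintf("  dominant reference frequency K = %d (of T = %d points)\n",
              x$K, x$T))
  cat(sprintf("  angular difference  = %s degrees\n",
              format(x$delta_angle, digits = digits)))
  cat(sprintf("  delay (initial %d)  = %d  [%s]\n", x$delta0, x$delta_star,
              switch(classify_delay(x$delta_star),
                     positive = "reference changes prior to query",
                     negative = "reference delayed w.r.t. query",
                     none = "no delay")))
  cat(sprintf("  realigned correlation r = %s on %d points (p = %s)\n",
              format(x$r_star, digits = digits), x$n_overlap,
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
summary.dynomics <- function(object, ...) {
  print(object, ...)
  if (!isTRUE(object$degenerate)) {
    r0 <- lagged_pearson(object$x, object$y, 0L)
    cat(sprintf("  correlation before realignment (lag 0): %s\n",
                format(r0, digits = 4)))
  }
  invisible(object)
}

#' @export
coef.dynomics <- function(object, ...) {
  c(delay = object$delta_star, correlation = object$r_star)
}

#' Plot a fitted trajectory pair before and after realignment
#'
#' @param x a fitted \code{"dynomics"} object.
#' @param ... further arguments passed to \code{matplot}.
#' @export
plot.dynomics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  scale01 <- function(v) if (stats::sd(v) == 0) v - mean(v) else
    (v - mean(v)) / stats::sd(v)
  graphics::matplot(cbind(scale01(x$x), scale01(x$y)), type = "b",
                    pch = c(1, 2), lty = 1, col = c(1, 2),
                    xlab = "time point", ylab = "standardised expression",
                    main = "original", ...)
  if (!isTRUE(x$degenerate)) {
    al <- align_trajectories(x$x, x$y, x$delta_star)
    graphics::matplot(cbind(scale01(al$x), scale01(al$y)), type = "b",
                      pch = c(1, 2), lty = 1, col = c(1, 2),
                      xlab = "time point (overlap)",
                      ylab = "standardised expression",
                      main = sprintf("realigned (delay %d, r = %.2f)",
                                     x$delta_star, x$r_star), ...)
  }
  invisible(x)
}
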