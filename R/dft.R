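#' Discrete Fourier components of a trajectory
#'
#' Decomposes an expression trajectory measured at T ordered, equally spaced
#' time points into its discrete Fourier components for frequencies
#' k = 1, ..., T - 1. The zero frequency only carries the overall expression
#' offset and is dropped. Each component is reported in polar form: real part
#' \code{a}, imaginary part \code{b}, amplitude \code{sqrt(a^2 + b^2)} and
#' phase angle in degrees mapped into [0, 360).
#'
#' The forward transform is \code{X_k = sum_t x_t exp(-2i pi k (t-1) / T)}
#' (the convention of \code{\link[stats]{fft}}, no 1/T scaling). Only phase
#' differences between two trajectories transformed with the same convention
#' matter downstream, so the choice of convention does not affect delay
#' estimates.
#'
#' @param x numeric vector of length T >= 4; expression values at equally
#'   spaced time points, no missing values.
#' @return a data.frame with one row per frequency k = 1..T-1 and columns
#'   \code{k}, \code{a}, \code{b}, \code{amplitude}, \code{phase_deg}.
#' @examples
#' x <- cos(2 * pi * (0:11) / 12)
#' comp <- dft_components(x)
#' comp$k[which.max(comp$amplitude)]
#' @seealso [dominant_frequency()], [dynomics()]
#' @export
dft_components <- function(x) {
  x <- as_trajectory(x)
  T <- length(x)
  X <- stats::fft(x)[-1L]                      # drop k = 0 (offset only)
  a <- Re(X)
  b <- Im(X)
  amplitude <- Mod(X)
  phase_deg <- (atan2(b, a) * 180 / pi) %% 360
  phase_deg[phase_deg >= 360] <- 0      # %% can return exactly 360 for -0-like angles
  data.frame(k = seq_len(T - 1L), a = a, b = b,
             amplitude = amplitude, phase_deg = phase_deg)
}

#' Dominant frequency of a set of Fourier components
#'
#' Returns the frequency index k with maximal amplitude, i.e. the cyclic
#' pattern that describes the main shape of the trajectory. Ties (within a
#' small relative tolerance, so that the mathematically equal amplitudes at
#' k and T - k of a real signal are treated as tied) are broken in favour of
#' the smallest k: the lowest frequency is the smoothest pattern and the
#' safest summary for short, noisy series.
#'
#' In a reference/query comparison the dominant frequency is always taken
#' from the reference trajectory.
#'
#' @param components data.frame as returned by [dft_components()].
#' @param tol relative tolerance for declaring two amplitudes tied.
#' @return integer frequency index K.
#' @export
dominant_frequency <- function(components, tol = 1e-8) {
  if (!is.data.frame(components) || nrow(components) == 0L)
    stop("'components' must be a nonempty data.frame from dft_components()")
  amp <- components$amplitude
  top <- max(amp)
  as.integer(components$k[which(amp >= top - tol * max(top, 1))[1L]])
}

# Validate a trajectory: numeric, length >= 4, all finite.
as_trajectory <- function(x, min_len = 4L) {
  if (is.data.frame(x)) x <- as.numeric(x[1L, ])
  x <- as.numeric(x)
  if (length(x) < min_len)
    stop("trajectory must have at least ", min_len, " time points, got ",
         length(x))
  if (any(!is.finite(x)))
    stop("trajectory contains non-finite values at positions: ",
         paste(which(!is.finite(x)), collapse = ", "))
  x
}
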