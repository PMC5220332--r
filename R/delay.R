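#' Angular difference between two phase angles
#'
#' Difference between the reference and query phase angles at a common
#' frequency, mapped into [0, 360) degrees. The angular difference jointly
#' encodes the sign of the correlation between the two trajectories and the
#' direction of any delay: values near 0 (or 360) indicate positive
#' correlation, values near 180 indicate negative correlation, and the
#' deviation from those anchors measures the delay.
#'
#' @param phase_ref_deg reference phase angle in degrees, in [0, 360).
#' @param phase_query_deg query phase angle in degrees, in [0, 360).
#' @return angular difference in degrees, in [0, 360).
#' @export
angular_difference <- function(phase_ref_deg, phase_query_deg) {
  (phase_ref_deg - phase_query_deg) %% 360
}

#' Initial delay estimate from an angular difference
#'
#' Converts the angular difference at the dominant reference frequency K into
#' an integer delay on the time grid. To keep delay estimates (and hence
#' signal shifts) as small as possible the angle is first collapsed:
#' \itemize{
#'   \item Delta in [0, 90): positive correlation, theta = Delta
#'   \item Delta in [90, 270): negative correlation, theta = Delta - 180
#'   \item Delta in [270, 360): positive correlation, theta = Delta - 360
#' }
#' and then scaled to time units, \code{delta0 = round(theta / 360 * T / K)},
#' rounding half away from zero. The collapsed angle lies in [-90, 90), so
#' \code{|delta0| <= T / (4 K)}.
#'
#' Sign convention: \code{delta0 > 0} means the reference changes expression
#' prior to the query (a "negative delay" of the query behind the reference);
#' \code{delta0 < 0} means the reference is delayed with respect to the query.
#'
#' @param delta_angle angular difference in degrees, in [0, 360).
#' @param T integer number of time points (>= 4).
#' @param K integer dominant frequency of the reference (>= 1).
#' @return signed integer initial delay estimate.
#' @export
initial_delay <- function(delta_angle, T, K) {
  if (length(K) != 1L || is.na(K) || K < 1)
    stop("'K' must be a positive integer frequency index")
  if (T < 4) stop("'T' must be at least 4")
  if (delta_angle < 0 || delta_angle >= 360)
    stop("'delta_angle' must lie in [0, 360)")
  theta <- if (delta_angle < 90) delta_angle
           else if (delta_angle < 270) delta_angle - 180
           else delta_angle - 360
  round_half_away(theta / 360 * T / K)
}

# round half away from zero ("rounded to the closest integer", symmetric in
# the delay sign) -- base round() rounds half to even.
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Shift a trajectory pair by a lag
#'
#' Offsets two equal-length trajectories against each other by the signed
#' integer lag \code{l} and truncates both to their T - |l| overlapping
#' points. A positive lag drops the tail of \code{x} and the head of
#' \code{y}, so it compensates a query that is delayed behind the reference;
#' a negative lag does the converse.
#'
#' @param x,y numeric vectors of common length T.
#' @param l signed integer lag with |l| <= T - 3 (at least 3 overlapping
#'   points must remain).
#' @return list with components \code{x} and \code{y}, each of length
#'   T - |l|.
#' @export
shift_pair <- function(x, y, l) {
  T <- length(x)
  if (length(y) != T) stop("'x' and 'y' must have the same length")
  l <- as.integer(l)
  if (abs(l) > T - 3L)
    stop("lag ", l, " leaves fewer than 3 overlapping points (T = ", T, ")")
  if (l == 0L) return(list(x = x, y = y))
  if (l < 0L) list(x = x[(1L - l):T], y = y[1L:(T + l)])
  else        list(x = x[1L:(T - l)], y = y[(1L + l):T])
}

#' Lagged Pearson correlation
#'
#' Pearson correlation between two trajectories after shifting them against
#' each other by lag \code{l} (see [shift_pair()]), computed on the
#' overlapping segment with segment means. If either shifted segment has zero
#' variance the correlation is undefined and \code{NA} is returned (screened
#' pairs with undefined correlation are reported as not associated, never
#' dropped silently).
#'
#' @inheritParams shift_pair
#' @return correlation in [-1, 1], or \code{NA} if undefined.
#' @export
lagged_pearson <- function(x, y, l) {
  s <- shift_pair(x, y, l)
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) return(NA_real_)
  stats::cor(s$x, s$y)
}

#' Refine a delay estimate by lagged correlation
#'
#' Starting from the initial Fourier-based delay estimate \code{delta0}, the
#' delay is refined in two stages, each maximising the absolute lagged
#' Pearson correlation so that both positively and negatively correlated
#' pairs are recovered:
#' \enumerate{
#'   \item compare \code{delta0} against the delay of the same size in the
#'     opposite direction, lag set \{delta0, -delta0\}, giving delta1;
#'   \item search the local neighbourhood \{delta1 - window, ...,
#'     delta1 + window\}, discarding lags that leave fewer than 3 overlapping
#'     points.
#' }
#' Ties in |r| are broken in favour of the smaller absolute lag, then the
#' more negative lag, keeping delay estimates as small as possible.
#' \code{delta0} is clamped into [-(T-3), T-3] before refinement.
#'
#' @inheritParams shift_pair
#' @param delta0 signed integer initial delay, e.g. from [initial_delay()].
#' @param window half-width of the stage-2 neighbourhood (default 1).
#' @return list with \code{delta_star} (refined integer delay), \code{r_star}
#'   (signed correlation at that delay) and \code{delta1} (the stage-1
#'   intermediate).
#' @export
refine_delay <- function(x, y, delta0, window = 1L) {
  T <- length(x)
  if (length(y) != T) stop("'x' and 'y' must have the same length")
  max_lag <- T - 3L
  delta0 <- max(min(as.integer(delta0), max_lag), -max_lag)

  lags1 <- unique(c(delta0, -delta0))
  d1 <- best_lag(x, y, lags1)
  if (is.na(d1$lag)) stop("delay estimation failed: no valid candidate lag")

  lags2 <- (d1$lag - as.integer(window)):(d1$lag + as.integer(window))
  lags2 <- lags2[abs(lags2) <= max_lag]
  d2 <- best_lag(x, y, lags2)
  if (is.na(d2$lag)) stop("delay estimation failed: no valid candidate lag")

  list(delta_star = d2$lag, r_star = d2$r, delta1 = d1$lag)
}

# argmax of |lagged_pearson| over a candidate lag set; ties by smaller |lag|,
# then more negative lag. NA correlations rank below everything.
best_lag <- function(x, y, lags) {
  r <- vapply(lags, function(l) lagged_pearson(x, y, l), numeric(1))
  score <- abs(r)
  score[is.na(score)] <- -Inf
  ord <- order(-score, abs(lags), lags)
  best <- ord[1L]
  if (!is.finite(score[best])) return(list(lag = NA_integer_, r = NA_real_))
  list(lag = lags[best], r = r[best])
}

#' Realign two trajectories by an estimated delay
#'
#' Applies the estimated delay as a lag and returns the overlapping,
#' realigned segments, e.g. for plotting or for clustering aligned profiles.
#'
#' @inheritParams shift_pair
#' @param delta_star signed integer delay, typically from [refine_delay()] or
#'   a fitted [dynomics()] object.
#' @return list with aligned components \code{x} and \code{y} of length
#'   T - |delta_star|.
#' @export
align_trajectories <- function(x, y, delta_star) {
  shift_pair(x, y, delta_star)
}
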