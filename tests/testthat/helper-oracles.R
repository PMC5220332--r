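# Independent oracles kept deliberately naive: they never share code with
# the implementation paths they check.

# Brute-force O(T^2) discrete Fourier transform, k = 0..T-1.
naive_dft <- function(x) {
  T <- length(x)
  vapply(0:(T - 1), function(k) {
    sum(complex(real = x) * exp(-2i * pi * k * (0:(T - 1)) / T))
  }, complex(1))
}

# Naive per-frequency components (k = 1..T-1) mirroring dft_components().
naive_components <- function(x) {
  X <- naive_dft(x)[-1]
  p <- (atan2(Im(X), Re(X)) * 180 / pi) %% 360
  p[p >= 360] <- 0
  data.frame(k = seq_along(X), a = Re(X), b = Im(X),
             amplitude = Mod(X), phase_deg = p)
}

# smallest signed angular distance between two sets of angles in degrees
circular_diff <- function(a, b) ((a - b + 180) %% 360) - 180

# Exhaustive lagged-correlation search over every lag leaving >= 3
# overlapping points, via direct segment construction (not shift_pair).
exhaustive_lag_search <- function(x, y) {
  T <- length(x)
  best <- list(lag = NA_integer_, r = -Inf)
  for (l in -(T - 3):(T - 3)) {
    if (l < 0) { xs <- x[(1 - l):T]; ys <- y[1:(T + l)] }
    else if (l > 0) { xs <- x[1:(T - l)]; ys <- y[(1 + l):T] }
    else { xs <- x; ys <- y }
    r <- suppressWarnings(cor(xs, ys))
    if (is.na(r)) next
    better <- abs(r) > abs(best$r) + 1e-12 ||
      (abs(abs(r) - abs(best$r)) <= 1e-12 && !is.na(best$lag) &&
         (abs(l) < abs(best$lag) ||
            (abs(l) == abs(best$lag) && l < best$lag)))
    if (is.infinite(best$r) || better) best <- list(lag = l, r = r)
  }
  best
}

# Hand-written Benjamini-Hochberg step-up: for each p, the minimum over the
# tail ranks of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Single-frequency cosine trajectory: frequency K cycles over T points,
# query delayed by s grid units relative to the reference.
cosine_traj <- function(T, K = 1, shift = 0, sign = 1) {
  t <- seq_len(T)
  sign * cos(2 * pi * K * (t - 1 - shift) / T)
}
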