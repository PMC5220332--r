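test_that("angular differences wrap into [0, 360)", {
  expect_equal(angular_difference(45, 45), 0)
  expect_equal(angular_difference(10, 40), 330)
  expect_equal(angular_difference(350, 20), 330)
  set.seed(3)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  d <- angular_difference(a, b)
  expect_true(all(d >= 0 & d < 360))
})

test_that("initial delay collapses the angular difference into a small signed lag", {
  # no delay, positive correlation
  expect_identical(initial_delay(0, 12, 1), 0L)
  expect_identical(initial_delay(0, 7, 2), 0L)
  # no delay, negative correlation (angle 180 collapses to 0)
  expect_identical(initial_delay(180, 12, 1), 0L)
  # quarter-turn boundary falls on the negative-correlation branch
  expect_identical(initial_delay(90, 12, 1), -3L)
  # reference prior to query by 2 of 12 points at K = 1
  expect_identical(initial_delay(60, 12, 1), 2L)
  # reference delayed with respect to query
  expect_identical(initial_delay(300, 12, 1), -2L)
  # higher dominant frequency scales the delay down
  expect_identical(initial_delay(60, 12, 2), 1L)
  expect_error(initial_delay(60, 12, 0), "positive integer")
  expect_error(initial_delay(-1, 12, 1), "0, 360")
})

test_that("half-integer initial delays round away from zero", {
  # theta/360 * T/K = 1.5 -> 2 ; and symmetric for the negative side
  expect_identical(initial_delay(45, 12, 1), 2L)
  expect_identical(initial_delay(315, 12, 1), -2L)
})

test_that("shift_pair trims trajectories per the lag sign", {
  x <- c(1, 2, 3, 4, 5); y <- c(9, 8, 7, 6, 5)
  expect_identical(shift_pair(x, y, 0), list(x = x, y = y))
  expect_identical(shift_pair(x, y, -2), list(x = c(3, 4, 5), y = c(9, 8, 7)))
  expect_identical(shift_pair(x, y, 2), list(x = c(1, 2, 3), y = c(7, 6, 5)))
  expect_error(shift_pair(x, y, 3), "overlapping")
  expect_error(shift_pair(x, y[-1], 0), "same length")
})

test_that("lagged correlation realigns shifted cosines exactly", {
  x <- cosine_traj(12)
  y <- cosine_traj(12, shift = 3)          # query delayed by 3
  expect_equal(lagged_pearson(x, x, 0), 1)
  expect_equal(lagged_pearson(x, -x, 0), -1)
  # a positive lag compensates a delayed query...
  expect_equal(lagged_pearson(x, y, 3), 1, tolerance = 1e-9)
  # ...while the opposite lag lands half a period out of phase
  expect_equal(lagged_pearson(x, y, -3), -1, tolerance = 1e-9)
  # zero-variance segment: undefined, not an error
  expect_true(is.na(lagged_pearson(rep(1, 6), rnorm(6), 0)))
})

test_that("refinement recovers noise-free delays and never worsens the fit", {
  x <- cosine_traj(14)
  y <- cosine_traj(14, shift = 2)
  ref <- refine_delay(x, y, initial_delay(
    angular_difference(dft_components(x)$phase_deg[1],
                       dft_components(y)$phase_deg[1]), 14, 1))
  expect_identical(ref$delta_star, 2L)
  expect_equal(ref$r_star, 1, tolerance = 1e-9)

  same <- refine_delay(x, x, 0)
  expect_identical(same$delta_star, 0L)
  expect_equal(same$r_star, 1)

  opp <- refine_delay(x, -x, 0)
  expect_identical(opp$delta_star, 0L)
  expect_equal(opp$r_star, -1)

  # monotone improvement over the initial estimate, random noisy pairs
  set.seed(21)
  for (i in 1:40) {
    T <- sample(7:14, 1)
    d0 <- sample(-(T - 3):(T - 3), 1)
    a <- rnorm(T); b <- rnorm(T)
    ref <- refine_delay(a, b, d0)
    expect_gte(abs(ref$r_star), abs(lagged_pearson(a, b, d0)) - 1e-12)
  }
})

test_that("out-of-range initial delays are clamped before refinement", {
  x <- rnorm(10); y <- rnorm(10)
  ref <- refine_delay(x, y, 25)
  expect_lte(abs(ref$delta_star), 7 + 1)   # clamp T-3 plus window
  expect_true(is.finite(ref$r_star))
})

test_that("full pipeline recovers shifts with the documented sign for all six angular cases", {
  # positive correlation, query delayed / simultaneous / reference delayed;
  # then the same three with a sign-flipped query
  for (T in c(12, 14)) {
    for (s in c(-2, 0, 2)) {
      for (sgn in c(1, -1)) {
        x <- cosine_traj(T)
        y <- cosine_traj(T, shift = s, sign = sgn)
        fit <- dynomics(x, y)
        expect_identical(fit$delta_star, as.integer(s))
        expect_equal(fit$r_star, sgn, tolerance = 1e-9)
        delta <- fit$delta_angle
        if (sgn > 0) expect_true(delta < 90 || delta >= 270)
        else expect_true(delta >= 90 && delta < 270)
      }
    }
  }
})

test_that("estimated delays stay within one unit of truth under modest noise", {
  set.seed(99)
  errs <- replicate(300, {
    s <- sample(-2:2, 1)
    x <- cosine_traj(14) + rnorm(14, 0, 0.1)
    y <- cosine_traj(14, shift = s) + rnorm(14, 0, 0.1)
    abs(dynomics(x, y)$delta_star - s)
  })
  expect_lte(mean(errs), 1)
})

test_that("alignment returns overlapping segments of the documented length", {
  x <- cosine_traj(14); y <- cosine_traj(14, shift = 2)
  al <- align_trajectories(x, y, -2)
  expect_length(al$x, 12)
  expect_length(al$y, 12)
  fit <- dynomics(x, y)
  al <- align_trajectories(x, y, fit$delta_star)
  expect_equal(cor(al$x, al$y), 1, tolerance = 1e-9)
})
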