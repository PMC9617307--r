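test_that("Bernoulli mapping gives the landmark pressure offsets", {
  expect_identical(bernoulli_dp(0), 0)
  expect_equal(bernoulli_dp(c(1, 2, 3)), c(4, 16, 36))
  expect_error(bernoulli_dp(-0.1), class = "mrlap_domain_error")
})

test_that("Weiss decay evaluates the exponential and rejects pre-reference times", {
  d <- weiss_decay(p_ref = 100, tau = 0.05)
  expect_equal(weiss_pressure(d, 0), 100)
  expect_equal(weiss_pressure(d, 0.05), 100 / exp(1))
  # the LAP = 10 case: pressure falls from LAP + 36 to LAP + 4
  d2 <- weiss_decay(p_ref = 46, tau = 0.05)
  expect_equal(weiss_pressure(d2, 0.05 * log(46 / 14)), 14, tolerance = 1e-10)
  expect_equal(weiss_pressure(d2, 0.0594792), 14, tolerance = 1e-5)
  # strictly decreasing
  tt <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(weiss_pressure(d, tt)) < 0))
  expect_error(weiss_pressure(d, -0.01), class = "mrlap_domain_error")
  expect_error(weiss_decay(p_ref = -1, tau = 0.05), class = "mrlap_domain_error")
})

test_that("tau recovery from pressure and decline rate is consistent with the decay model", {
  expect_equal(tau_from_pressure_rate(100, -2000), 0.05)
  expect_equal(tau_from_pressure_rate(46, -920), 0.05)
  expect_error(tau_from_pressure_rate(100, 10), class = "mrlap_domain_error")
  # P'(t) = -P(t)/tau for the exponential, so the ratio recovers tau anywhere
  set.seed(7)
  for (i in 1:20) {
    tau <- runif(1, 0.02, 0.12)
    d <- weiss_decay(p_ref = runif(1, 40, 150), tau = tau)
    t <- runif(1, 0, 0.2)
    p <- weiss_pressure(d, t)
    expect_equal(tau_from_pressure_rate(p, -p / tau), tau, tolerance = 1e-12)
  }
})

test_that("forward descent intervals match direct evaluation and scale in tau", {
  f <- forward_descent_intervals(10, 0.05)
  expect_equal(f$d12, 0.0309519604, tolerance = 1e-8)
  expect_equal(f$d13, 0.0594792033, tolerance = 1e-8)
  f2 <- forward_descent_intervals(10, 0.10)
  expect_equal(f2$d12, 2 * f$d12)
  expect_equal(f2$d13, 2 * f$d13)
  # LAP -> 0 limit of the interval ratio
  f0 <- forward_descent_intervals(1e-9, 0.05)
  expect_equal(f0$d13 / f0$d12, log(9) / log(4), tolerance = 1e-8)
  # ratio strictly inside (ln9/ln4, 8/3)
  for (L in c(0.5, 5, 50, 190)) {
    fi <- forward_descent_intervals(L, 0.06)
    r <- fi$d13 / fi$d12
    expect_gt(r, log(9) / log(4))
    expect_lt(r, 8 / 3)
  }
})

test_that("solver recovers the generating (lap, tau) and verifies both equations", {
  times <- descent_times(t1 = 0.059479, t2 = 0.059479 - 0.030952, t3 = 0)
  est <- solve_lap_eq(times)
  expect_s3_class(est, "lap_estimate")
  expect_equal(est$lap, 10, tolerance = 1e-3)
  expect_equal(est$tau, 0.05, tolerance = 1e-4)
  expect_identical(est$method, "Eq")
  expect_true(est$diagnostics$converged)
  # both interval equations hold by substitution
  expect_equal(times$t1 - times$t3, est$tau * log((est$lap + 36) / (est$lap + 4)),
               tolerance = 1e-6)
  expect_equal(times$t1 - times$t2, est$tau * log((est$lap + 16) / (est$lap + 4)),
               tolerance = 1e-6)
})

test_that("solver round-trips the forward model over the physiologic grid", {
  for (lap in seq(2, 40, by = 2)) {
    for (tau in seq(0.02, 0.12, by = 0.01)) {
      f <- forward_descent_intervals(lap, tau)
      est <- solve_lap_eq(descent_times(t1 = f$d13, t2 = f$d13 - f$d12, t3 = 0))
      expect_equal(est$lap, lap, tolerance = 1e-4)
      expect_equal(est$tau, tau, tolerance = 1e-6)
    }
  }
})

test_that("infeasible interval ratios are rejected, boundary solves to LAP ~ 0", {
  # ratio 1.50 lies below the LAP = 0 limit ln9/ln4
  expect_error(solve_lap_eq(descent_times(t1 = 1.5, t2 = 0.5, t3 = 0)),
               class = "mrlap_infeasible_geometry")
  # ratio at/above the asymptotic bound 8/3
  expect_error(solve_lap_eq(descent_times(t1 = 8, t2 = 5, t3 = 0)),
               class = "mrlap_infeasible_geometry")
  # ratio at the lower boundary (forward model at tiny LAP) solves to ~0
  f <- forward_descent_intervals(1e-6, 0.05)
  est <- solve_lap_eq(descent_times(t1 = f$d13, t2 = f$d13 - f$d12, t3 = 0))
  expect_lt(est$lap, 1e-3)
})

test_that("g(L) is strictly increasing on [0, 200] with the stated limits", {
  g <- function(L) log((L + 36) / (L + 4)) / log((L + 16) / (L + 4))
  L <- seq(0, 200, by = 0.1)
  expect_true(all(diff(g(L)) > 0))
  expect_equal(g(0), log(9) / log(4))
  expect_lt(g(200), 8 / 3)
  expect_equal(g(1e9), 8 / 3, tolerance = 1e-6)
})

test_that("scaling all descent spacings by k leaves LAP unchanged and scales tau", {
  set.seed(11)
  for (i in 1:10) {
    lap <- runif(1, 2, 35)
    tau <- runif(1, 0.03, 0.1)
    k <- runif(1, 0.3, 3)
    f <- forward_descent_intervals(lap, tau)
    e1 <- solve_lap_eq(descent_times(t1 = f$d13, t2 = f$d13 - f$d12, t3 = 0))
    e2 <- solve_lap_eq(descent_times(t1 = k * f$d13, t2 = k * (f$d13 - f$d12), t3 = 0))
    expect_equal(e2$lap, e1$lap, tolerance = 1e-5)
    expect_equal(e2$tau, k * e1$tau, tolerance = 1e-6)
  }
})

test_that("eccentric velocity underestimation biases LAP_BP far more than LAP_Eq", {
  lap <- 10; tau <- 0.05; v_peak <- 4.9; p_sys <- 111
  for (c in seq(0.85, 0.99, by = 0.02)) {
    f <- eccentric_intervals(lap, tau, c)
    eq <- solve_lap_eq(descent_times(t1 = f$d13, t2 = f$d13 - f$d12, t3 = 0))
    bias_eq <- eq$lap - lap
    # LAP_BP bias relative to its own unbiased value: 4 v^2 (1 - c^2)
    bp_meas <- suppressWarnings(lap_bp(p_sys, c * v_peak))$lap
    bp_true <- lap_bp(p_sys, v_peak)$lap
    bias_bp <- bp_meas - bp_true
    expect_equal(bias_bp, 4 * v_peak^2 * (1 - c^2), tolerance = 1e-9)
    expect_lt(abs(bias_eq), abs(bias_bp))
  }
  # spot values at c = 0.9
  f <- eccentric_intervals(10, 0.05, 0.9)
  eq <- solve_lap_eq(descent_times(t1 = f$d13, t2 = f$d13 - f$d12, t3 = 0))
  expect_equal(eq$lap - 10, -2, tolerance = 0.15)
  expect_equal(4 * 4.9^2 * (1 - 0.9^2), 18.2476, tolerance = 1e-4)
})

test_that("sphygmomanometer estimate subtracts the peak gradient and flags negatives", {
  est <- lap_bp(111, 4.9)
  expect_equal(est$lap, 14.96)
  expect_identical(est$method, "BP")
  expect_true(is.na(est$tau))
  expect_equal(lap_bp(100, 5)$lap, 0)
  expect_warning(neg <- lap_bp(96, 5), class = "mrlap_implausible_value")
  expect_equal(neg$lap, -4)
  expect_true("implausible_negative" %in% neg$flags)
  expect_error(lap_bp(-10, 4), class = "mrlap_domain_error")
})
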