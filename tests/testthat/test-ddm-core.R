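test_that("parameter validation rejects out-of-domain values", {
  expect_error(ddm_params(v = 1, a = 0), "a")
  expect_error(ddm_params(v = 1, a = 1, z = 0), "z")
  expect_error(ddm_params(v = 1, a = 1, z = 1), "z")
  expect_error(ddm_params(v = 1, a = 1, t0 = -0.1), "t0")
  expect_error(ddm_params(v = 1, a = 1, s = 0), "s")
})

test_that("density is zero up to non-decision time and symmetric when v = 0, z = 0.5", {
  p <- ddm_params(v = 0, a = 1.5, z = 0.5, t0 = 0.2)
  expect_equal(wfpt_density(c(0.05, 0.2), "upper", p), c(0, 0))
  ts <- seq(0.21, 2, by = 0.05)
  expect_equal(wfpt_density(ts, "upper", p), wfpt_density(ts, "lower", p))
})

test_that("density is invariant under the (v, z, boundary) reflection", {
  for (p in param_grid()[1:6]) {
    pr <- ddm_params(v = -p$v, a = p$a, z = 1 - p$z, t0 = p$t0, s = p$s)
    ts <- p$t0 + c(0.01, 0.05, 0.2, 0.5, 1.5)
    expect_equal(wfpt_density(ts, "upper", p),
                 wfpt_density(ts, "lower", pr), tolerance = 1e-12)
  }
})

test_that("defective densities integrate to the closed-form absorption probabilities", {
  for (p in param_grid()) {
    iu <- integrate_density("upper", p)
    il <- integrate_density("lower", p)
    expect_equal(iu + il, 1, tolerance = 1e-4)
    expect_equal(iu, absorption_probability("upper", p), tolerance = 1e-4)
  }
})

test_that("absorption probability has the v -> 0 limit z and complements to 1", {
  expect_equal(absorption_probability("upper",
                                      ddm_params(v = 0, a = 1, z = 0.5)), 0.5)
  expect_equal(absorption_probability("upper",
                                      ddm_params(v = 0, a = 1, z = 0.7)), 0.7)
  for (p in param_grid()) {
    expect_equal(absorption_probability("upper", p) +
                   absorption_probability("lower", p), 1)
    # continuity of the v -> 0 limit
    eps <- ddm_params(v = 1e-7, a = p$a, z = p$z, t0 = p$t0)
    lim <- ddm_params(v = 0, a = p$a, z = p$z, t0 = p$t0)
    expect_equal(absorption_probability("upper", eps),
                 absorption_probability("upper", lim), tolerance = 1e-6)
  }
})

test_that("small-time and large-time series branches agree at the switch point", {
  for (p in list(ddm_params(v = 0.8, a = 1, z = 0.4, t0 = 0),
                 ddm_params(v = -1.5, a = 1.6, z = 0.6, t0 = 0),
                 ddm_params(v = 2.0, a = 0.8, z = 0.3, t0 = 0))) {
    tt <- seq(0.005, 3, by = 1e-4)
    br <- gazecue:::wfpt_branch_cpp(tt / p$a^2)
    sw <- tt[which(diff(br) != 0)[1] + 1L]
    small <- gazecue:::wfpt_density_forced_cpp(sw, p$v, p$a, p$z, 0, 1, 1L)
    large <- gazecue:::wfpt_density_forced_cpp(sw, p$v, p$a, p$z, 0, 1, 2L)
    expect_lt(abs(small - large), 1e-8)
    # and the adaptive evaluation equals whichever branch it picked
    expect_equal(wfpt_density(sw, "lower", p), small, tolerance = 1e-8)
  }
})

test_that("simulator is seed-deterministic, respects t0, and validates arguments", {
  p <- ddm_params(v = 1.2, a = 1.1, z = 0.5, t0 = 0.25)
  s1 <- simulate_ddm(p, 100, dt = 1e-3, seed = 5)
  s2 <- simulate_ddm(p, 100, dt = 1e-3, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$rt > 0.25))
  expect_error(simulate_ddm(p, 0), "n")
  expect_error(simulate_ddm(p, 10, dt = 0), "dt")
})

test_that("simulated choices and response times match the analytic law", {
  p <- ddm_params(v = 1.5, a = 1.0, z = 0.5, t0 = 0.3)
  n <- 2e4
  sim <- simulate_ddm(p, n, dt = 1e-4, seed = 11)
  pu <- absorption_probability("upper", p)
  se <- sqrt(pu * (1 - pu) / n)
  expect_lt(abs(mean(sim$boundary == "upper") - pu), 3 * se)
  up <- sort(sim$rt[sim$boundary == "upper"])
  Fa <- wfpt_cdf(up, "upper", p) / integrate_density("upper", p)
  ks <- max(abs(Fa - seq_along(up) / length(up)))
  expect_lt(ks, 0.015) # 1e5-trial acceptance run tightens this to 0.01
})

test_that("simulator mean decision time matches the analytic mean by quadrature", {
  p <- ddm_params(v = 0, a = 1.2, z = 0.5, t0 = 0.2)
  m_quad <- stats::integrate(function(t)
    t * (wfpt_density(t, "upper", p) + wfpt_density(t, "lower", p)),
    p$t0, Inf, rel.tol = 1e-9)$value - p$t0
  # unbiased symmetric walk: E[T] = z a (a - z a) / s^2 = a^2 / 4
  expect_equal(m_quad, p$a^2 / 4, tolerance = 1e-6)
  sim <- simulate_ddm(p, 1e4, dt = 1e-4, seed = 3)
  dec <- sim$rt - p$t0
  expect_lt(abs(mean(dec) - m_quad), 3 * stats::sd(dec) / sqrt(length(dec)))
})

test_that("floored log density clamps out-of-support times and inverts exp", {
  p <- ddm_params(v = 1, a = 1.2, z = 0.5, t0 = 0.3)
  expect_equal(trial_log_density(c(0.1, 0.3), "upper", p), c(-700, -700))
  expect_equal(trial_log_density(0.2, "upper", p, floor = -50), -50)
  ts <- c(0.35, 0.5, 0.9)
  expect_equal(exp(trial_log_density(ts, "upper", p)),
               wfpt_density(ts, "upper", p))
  expect_error(trial_log_density(-1, "upper", p), "rt")
})
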