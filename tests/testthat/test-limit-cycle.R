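test_that("the outer bound solves the nullcline intersection", {
  p <- slow_params(1.5)  # f*eta_m = 1.11
  ms <- m_star(p)
  # independent oracle: root-find the nullcline equation
  # -f*m = (f - k/eta_m)*m - (k3/eta_m)*m^3 directly
  g <- function(m) (p$f - p$k / p$eta_m_plus) * m -
    (p$k3 / p$eta_m_plus) * m^3 + p$f * m
  root <- uniroot(g, c(1, 1000), tol = 1e-12)$root
  expect_equal(ms, root, tolerance = 1e-9)
  expect_equal(ms, 25.70436, tolerance = 1e-6)
  # square-root scaling in the strong-sensitivity limit
  p4 <- mood_params(eta_m_plus = 400 * p$eta_m_plus, eta_v = p$eta_v,
                    f = p$f, k = p$k, k3 = p$k3)
  p1 <- mood_params(eta_m_plus = 100 * p$eta_m_plus, eta_v = p$eta_v,
                    f = p$f, k = p$k, k3 = p$k3)
  expect_equal(m_star(p4) / m_star(p1), 2, tolerance = 1e-3)
  # asymmetric parameters are rejected
  expect_error(m_star(slow_params(1.5, 1.2)), "symmetric")
  # below the degenerate root there is no positive intersection
  p_low <- mood_params(eta_m_plus = 0.1, eta_v = 0.37, f = 0.3, k = 0.37,
                       k3 = 2.8e-3)
  expect_error(m_star(p_low), "positive")
})

test_that("cycle extraction recovers a known synthetic oscillation", {
  tt <- seq(0, 200, by = 0.05)
  traj <- data.frame(time = tt, m = 3 * sin(2 * pi * tt / 17),
                     v = 0 * tt, r = 0 * tt, branch = 1L)
  class(traj) <- c("mood_trajectory", "data.frame")
  cyc <- estimate_cycle(traj)
  expect_true(cyc$converged)
  expect_equal(cyc$amplitude, 3, tolerance = 1e-4)
  expect_equal(cyc$period, 17, tolerance = 1e-4)
  expect_equal(cyc$mood_sd, 3 / sqrt(2), tolerance = 0.02)
})

test_that("a decayed trajectory yields near-zero amplitude and sd", {
  traj <- simulate_mood(slow_params(0.3), constant_reality(0, 150),
                        init = c(0, -1))
  cyc <- estimate_cycle(traj)
  expect_lt(cyc$amplitude, 1e-3)
  expect_lt(cyc$mood_sd, 1e-3)
})

test_that("the converged cycle respects the outer bound", {
  p <- slow_params(1.5)
  traj <- simulate_mood(p, constant_reality(0, 300), init = c(0, -1))
  cyc <- estimate_cycle(traj)
  expect_true(cyc$converged)
  expect_lte(cyc$amplitude, m_star(p))
})

test_that("the cycle period near threshold approaches the Hopf period", {
  # at onset the frequency is Im(lambda) = sqrt(eta_v*k): period 16.98 wk
  p <- slow_params(1.01)
  traj <- simulate_mood(p, constant_reality(0, 250), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.05))
  cyc <- estimate_cycle(traj, assessment_fraction = 0.8)
  expect_equal(cyc$period, 2 * pi / sqrt(0.37 * 0.37), tolerance = 0.02)
})

test_that("the analytic Hopf threshold is the sum of eta_v and k", {
  expect_equal(hopf_threshold(slow_params(1.5)), 0.74)
  expect_equal(hopf_threshold(map_params(1)), 1.85)
})

test_that("amplitude grows with sensitivity and stays below the bound", {
  p <- slow_params(1.5)
  scan <- amplitude_scan(p, f_eta_m_values = c(1.5, 3, 6) * 0.74,
                         horizon = 200,
                         opts = solver_options(grid_dt = 0.1))
  expect_true(all(scan$converged))
  expect_true(all(scan$amplitude <= scan$m_star))
  expect_true(all(diff(scan$amplitude) > 0))
  expect_error(amplitude_scan(p, c(0.5, 2) * 0.74), "supra-threshold")
})

test_that("random-reality mood variability is larger above threshold", {
  r <- random_reality(2, 1, seed = 77, horizon = 150)
  sub <- simulate_mood(slow_params(0.3), r, init = c(0, 0),
                       opts = solver_options(grid_dt = 0.1))
  supra <- simulate_mood(slow_params(1.5), r, init = c(0, 0),
                         opts = solver_options(grid_dt = 0.1))
  expect_lt(estimate_cycle(sub)$mood_sd, estimate_cycle(supra)$mood_sd)
})

test_that("stability scans are reproducible and self-consistent", {
  ratios <- seq(0.4, 1.6, length.out = 4)
  scan1 <- stability_scan(eta_v = 1.48, f = 0.3, k = 0.37, k3 = 2.8e-3,
                          ratios_plus = ratios, ratios_minus = ratios,
                          horizon = 80)
  scan2 <- stability_scan(eta_v = 1.48, f = 0.3, k = 0.37, k3 = 2.8e-3,
                          ratios_plus = ratios, ratios_minus = ratios,
                          horizon = 80)
  expect_identical(scan1$mood_sd, scan2$mood_sd)
  expect_equal(nrow(scan1), 16L)
  expect_true(all(c("mood_sd", "empirical_call", "analytic_verdict")
                  %in% names(scan1)))
  # the most extreme corners are called correctly even on a short horizon
  low <- scan1[scan1$ratio_plus == 0.4 & scan1$ratio_minus == 0.4, ]
  hi <- scan1[scan1$ratio_plus == 1.6 & scan1$ratio_minus == 1.6, ]
  expect_equal(low$empirical_call, "stable")
  expect_equal(hi$empirical_call, "unstable")
})
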