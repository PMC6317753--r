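test_that("closed-form eigenvalues satisfy trace/determinant identities", {
  set.seed(101)
  for (i in 1:1000) {
    p <- random_params()
    for (br in c("plus", "minus")) {
      e <- eigen_report(p, br)
      fe <- p$f * (if (br == "plus") p$eta_m_plus else p$eta_m_minus)
      tr <- fe - p$eta_v - p$k
      expect_equal(Re(e$lambda_plus + e$lambda_minus), tr,
                   tolerance = 1e-12)
      expect_equal(Re(e$lambda_plus * e$lambda_minus), p$eta_v * p$k,
                   tolerance = 1e-12)
    }
  }
})

test_that("closed-form eigenvalues match numerical eigendecomposition", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    p <- random_params()
    e <- eigen_report(p, "plus")
    num <- eigen(branch_jacobian(p, "plus"), only.values = TRUE)$values
    got <- sort(c(e$lambda_plus, e$lambda_minus))
    ref <- sort(as.complex(num))
    worst <- max(worst, max(Mod(got - ref)))
  }
  expect_lt(worst, 1e-10)
})

test_that("threshold and dissipation-free cases behave as the theory says", {
  # at the critical sensitivity the eigenvalues are purely imaginary
  e <- eigen_closed_form(0.74, eta_v = 0.37, k = 0.37)
  expect_equal(Re(e$lambda_plus), 0)
  expect_equal(e$discriminant, -4 * 0.37 * 0.37)
  expect_equal(Im(e$lambda_plus), 0.37)
  # without linear dissipation (k = 0) the eigenvalues are always real
  for (fe in c(0.05, 0.3, 0.74, 2, 10)) {
    e0 <- eigen_closed_form(fe, eta_v = 0.37, k = 0)
    expect_gte(e0$discriminant, 0)
    expect_identical(Im(e0$lambda_plus), 0)
    expect_identical(Im(e0$lambda_minus), 0)
  }
})

test_that("half-plane regimes partition the sensitivity axis", {
  # eta_v = 1.48, k = 0.37: critical 1.85, spiral window half-width 1.48
  expect_equal(classify_halfplane(map_params(1.2, 1), "plus"),
               "unstable_spiral")  # f*eta_m = 2.22
  expect_equal(classify_halfplane(map_params(0.108108108, 1), "plus"),
               "stable_node")      # f*eta_m = 0.2 < 0.37
  expect_equal(classify_halfplane(map_params(1, 0.5), "minus"),
               "stable_spiral")
  expect_equal(classify_halfplane(map_params(2.1, 1), "plus"),
               "unstable_node")    # f*eta_m = 3.885 > 3.33
  # exact boundaries are flagged, not classified
  expect_equal(as.character(classify_halfplane(map_params(1, 1), "plus")),
               "degenerate")
  p_edge <- mood_params(eta_m_plus = (1.85 + 1.48) / 0.3, eta_v = 1.48,
                        f = 0.3, k = 0.37, k3 = 2.8e-3)
  expect_equal(as.character(classify_halfplane(p_edge, "plus")),
               "degenerate")
})

test_that("the half-cycle multiplier matches its closed form and symmetry", {
  # eta_v = 1.48, k = 0.37, f*eta_m+ = 2.22: factor about 2.2505
  p <- map_params(1.2, 1)
  expect_equal(half_cycle_multiplier(p, "plus"), 2.2505, tolerance = 1e-4)
  # multiplier is 1 exactly at threshold-symmetric displacements x and -x
  for (x in c(0.2, 0.5, 1.0, 1.4)) {
    hi <- mood_params(eta_m_plus = (1.85 + x) / 0.3, eta_v = 1.48, f = 0.3,
                      k = 0.37, k3 = 2.8e-3)
    lo <- mood_params(eta_m_plus = (1.85 - x) / 0.3, eta_v = 1.48, f = 0.3,
                      k = 0.37, k3 = 2.8e-3)
    expect_equal(half_cycle_multiplier(hi, "plus") *
                 half_cycle_multiplier(lo, "plus"), 1, tolerance = 1e-12)
  }
  # not defined for nodes
  expect_error(half_cycle_multiplier(map_params(2.1, 1), "plus"), "spiral")
})

test_that("the spiral-spiral criterion vanishes on the symmetry line", {
  # f*(eta_m+ + eta_m-) = 2*(eta_v + k): ratios 1.2 and 0.8
  p <- map_params(1.2, 0.8)
  expect_equal(spiral_stability_criterion(p), 0, tolerance = 1e-12)
  # symmetric subthreshold spirals: strictly negative
  expect_lt(spiral_stability_criterion(map_params(0.6, 0.6)), 0)
  # log of the product of half-cycle multipliers equals the criterion
  set.seed(303)
  for (i in 1:50) {
    p <- random_params(spiral = TRUE)
    lp <- log(half_cycle_multiplier(p, "plus") *
              half_cycle_multiplier(p, "minus"))
    expect_equal(lp, spiral_stability_criterion(p), tolerance = 1e-10)
  }
  expect_error(spiral_stability_criterion(map_params(2.1, 0.5)), "spiral")
})

test_that("the stability decision table covers every regime pairing", {
  # both subthreshold: stable
  r <- predict_stability(map_params(0.4, 0.4))
  expect_equal(r$verdict, "stable")
  # both above: unstable
  expect_equal(predict_stability(map_params(2, 2))$verdict, "unstable")
  # unstable spiral + stable node: the node wins -> stable
  r2 <- predict_stability(map_params(1.2, 0.108108108))
  expect_equal(r2$regime_plus, "unstable_spiral")
  expect_equal(r2$regime_minus, "stable_node")
  expect_equal(r2$verdict, "stable")
  expect_equal(r2$rule_used, "node_dominates_spiral")
  # stable spiral + unstable node -> unstable
  r3 <- predict_stability(map_params(2.1, 0.5))
  expect_equal(r3$verdict, "unstable")
  # spiral-spiral decided by the full-cycle multiplier
  r4 <- predict_stability(map_params(1.2, 0.7))  # sum of ratios < 2
  expect_equal(r4$rule_used, "spiral_spiral_full_cycle_multiplier")
  expect_equal(r4$verdict, "stable")
  expect_equal(predict_stability(map_params(1.2, 0.9))$verdict, "unstable")
  # stable node + unstable node: reported unstable, flagged IC-sensitive
  r5 <- predict_stability(map_params(2.1, 0.10810810))
  expect_equal(r5$verdict, "unstable")
  expect_true(r5$initial_condition_sensitive)
  # boundary parameters flagged degenerate
  expect_equal(predict_stability(map_params(1, 0.5))$verdict, "degenerate")
})

test_that("the piecewise-linear integrator matches the matrix exponential", {
  p <- slow_params(0.6)  # symmetric subthreshold: single linear system
  times <- seq(0, 60, by = 0.5)
  traj <- simulate_linearized(p, init = c(0.4, -1), horizon = 60,
                              opts = solver_options(rel_tol = 1e-12,
                                                    abs_tol = 1e-14,
                                                    grid_dt = 0.5))
  ref <- linear_solution(p, "plus", c(0.4, -1), times)
  expect_lt(max(abs(traj$m - ref[, 1L])), 1e-8)
  expect_lt(max(abs(traj$v - ref[, 2L])), 1e-8)
})

test_that("linearized distance ratios reproduce the half-cycle multiplier", {
  set.seed(404)
  worst <- 0
  for (i in 1:10) {
    p <- random_params(spiral = TRUE)
    dt <- moodcycle:::half_cycle_time(p, "plus")
    o <- solver_options(rel_tol = 1e-12, abs_tol = 1e-14,
                        grid_dt = dt / 400)
    # start on the boundary at m0 < 0: the surface drift carries the
    # trajectory into the positive half-plane for the next half cycle
    init <- c(-1, -p$f)
    traj <- simulate_linearized(p, init = init, horizon = dt, opts = o)
    n <- nrow(traj)
    ratio <- sqrt(traj$m[n]^2 + traj$v[n]^2) / sqrt(sum(init^2))
    worst <- max(worst, abs(ratio / half_cycle_multiplier(p, "plus") - 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("damped oscillation frequency equals the eigenvalue prediction", {
  p <- slow_params(0.6)
  e <- eigen_report(p, "plus")
  omega <- sqrt(-e$discriminant) / 2
  traj <- simulate_mood(p, constant_reality(0, 120), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.02))
  # period from successive mood zero crossings (half-period apart)
  sgn <- sign(traj$m)
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  tc <- traj$time[cross]
  measured_omega <- pi / mean(diff(tc))
  expect_equal(measured_omega, omega, tolerance = 0.02)
})
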