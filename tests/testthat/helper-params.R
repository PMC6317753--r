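# canonical parameter sets used across the tests: the slow-learning
# configuration (eta_v = k = 0.37 per week, f = 0.3, k3 = 2.8e-3) and the
# fast-expectation configuration used for the two-parameter stability map
# (eta_v = 1.48, k = 0.37)
slow_params <- function(ratio_plus, ratio_minus = ratio_plus) {
  mood_params_from_ratios(ratio_plus, eta_v = 0.37, f = 0.3, k = 0.37,
                          k3 = 2.8e-3, ratio_minus = ratio_minus)
}

map_params <- function(ratio_plus, ratio_minus = ratio_plus) {
  mood_params_from_ratios(ratio_plus, eta_v = 1.48, f = 0.3, k = 0.37,
                          k3 = 2.8e-3, ratio_minus = ratio_minus)
}

# Jacobian of the linearized system for one learning-rate branch; the
# generic numerical eigendecomposition of this matrix is the oracle for
# the closed-form eigenvalues
branch_jacobian <- function(params, branch = "plus") {
  eta <- if (branch == "plus") params$eta_m_plus else params$eta_m_minus
  matrix(c(params$f * eta - params$k, params$f * params$eta_v,
           -eta, -params$eta_v), 2L, 2L)
}

# random parameter draw; optionally constrained so both half-planes are
# spirals (complex eigenvalues on both branches)
random_params <- function(spiral = FALSE) {
  repeat {
    eta_v <- runif(1, 0.05, 3); k <- runif(1, 0.05, 3)
    f <- runif(1, 0.1, 1)
    if (spiral) {
      crit <- eta_v + k; w <- 2 * sqrt(eta_v * k)
      fe_p <- runif(1, crit - 0.95 * w, crit + 0.95 * w)
      fe_m <- runif(1, crit - 0.95 * w, crit + 0.95 * w)
    } else {
      fe_p <- runif(1, 0.05, 6); fe_m <- runif(1, 0.05, 6)
    }
    if (fe_p <= 0 || fe_m <= 0) next
    return(mood_params(eta_m_plus = fe_p / f, eta_v = eta_v, f = f, k = k,
                       k3 = runif(1, 1e-3, 1e-1), eta_m_minus = fe_m / f))
  }
}

# closed-form linear solution via matrix exponential (eigendecomposition),
# independent of the package's integrator
linear_solution <- function(params, branch, y0, times) {
  A <- branch_jacobian(params, branch)
  ev <- eigen(A)
  Vi <- solve(ev$vectors)
  t(vapply(times, function(t) {
    Re(ev$vectors %*% diag(exp(ev$values * t)) %*% Vi %*% y0)[, 1L]
  }, numeric(2)))
}
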