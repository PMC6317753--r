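#' Surprise (prediction error) signal
#'
#' The surprise `f*m + r - v` is the mismatch between perceived reality
#' (reality `r` additively biased by mood through `f*m`) and the learned
#' expectation `v`. Its sign selects the active mood learning rate when the
#' sensitivities are asymmetric.
#'
#' @param m mood value(s).
#' @param v expectation value(s).
#' @param r reality value(s).
#' @param params a [mood_params()] object.
#' @return Numeric surprise value(s), in reality units.
#' @export
surprise <- function(m, v, r, params) {
  params$f * m + r - v
}

#' Active mood learning rate
#'
#' Selects the mood learning rate according to the sign of the surprise:
#' `eta_m_plus` for strictly positive surprise, `eta_m_minus` otherwise
#' (the boundary `f*m + r - v = 0` belongs to the minus branch).
#'
#' @inheritParams surprise
#' @return The active learning rate(s) (1/week), vectorised over the inputs.
#' @examples
#' p <- mood_params(0.9, eta_v = 0.37, f = 0.3, k = 0.37, k3 = 2.8e-3,
#'                  eta_m_minus = 0.4)
#' select_eta_m(m = 0, v = -1, r = 0, params = p)  # positive surprise
#' select_eta_m(m = 0, v = 0, r = 0, params = p)   # boundary: minus branch
#' @export
select_eta_m <- function(m, v, r, params) {
  ifelse(surprise(m, v, r, params) > 0, params$eta_m_plus, params$eta_m_minus)
}

#' Right-hand side of the mood-expectation system
#'
#' Time derivatives of the first-order system: mood is driven by surprise at
#' the active learning rate and relaxed by linear and cubic recovery;
#' expectation tracks perceived reality,
#' \deqn{dm/dt = \eta_m (fm + r - v) - km - k_3 m^3, \quad
#'       dv/dt = \eta_v (fm + r - v).}
#'
#' @param state numeric vector `c(m, v)`.
#' @param r reality value at the current time.
#' @param params a [mood_params()] object.
#' @return Numeric vector `c(dm, dv)` (per week).
#' @examples
#' p <- mood_params(0.74 / 0.3, eta_v = 0.37, f = 0.3, k = 0.37, k3 = 2.8e-3)
#' mood_rhs(c(0, 0), r = 0, params = p)  # the fixed point
#' @export
mood_rhs <- function(state, r, params) {
  if (any(!is.finite(state)))
    stop("non-finite state passed to mood_rhs (integrator divergence?)")
  m <- state[[1]]; v <- state[[2]]
  s <- params$f * m + r - v
  eta <- if (s > 0) params$eta_m_plus else params$eta_m_minus
  c(eta * s - params$k * m - params$k3 * m^3,
    params$eta_v * s)
}

#' Second-order (Lienard) form of the mood equation
#'
#' For symmetric sensitivities and differentiable reality, eliminating the
#' expectation turns the system into a single Lienard-type oscillator in
#' mood:
#' \deqn{\ddot m = (f\eta_m - k - \eta_v - 3 k_3 m^2)\,\dot m
#'       - \eta_v k\, m - \eta_v k_3\, m^3 + \eta_m\, \dot r.}
#' The nonlinear damping coefficient changes sign with `|m|`, the van der
#' Pol mechanism that sustains the limit cycle above the Hopf threshold.
#'
#' @param m mood.
#' @param dm first derivative of mood (1/week).
#' @param dr time derivative of reality (reality units/week).
#' @param params a symmetric [mood_params()] object; the second-order form
#'   is undefined when the learning rate switches with the surprise sign.
#' @return The mood acceleration `d2m/dt2`.
#' @export
lienard_rhs <- function(m, dm, dr, params) {
  if (!is_symmetric(params))
    stop("the Lienard form requires symmetric mood sensitivities ",
         "(eta_m_plus == eta_m_minus)")
  fe <- params$f * params$eta_m_plus
  (fe - params$k - params$eta_v - 3 * params$k3 * m^2) * dm -
    params$eta_v * params$k * m - params$eta_v * params$k3 * m^3 +
    params$eta_m_plus * dr
}
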