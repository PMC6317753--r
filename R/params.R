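#' Model parameters for the mood-expectation system
#'
#' Bundles the six rate constants of the mood-expectation model. Mood `m`
#' relaxes at a linear rate `k` and a cubic rate `k3` while being driven by
#' the surprise signal `f*m + r - v` at learning rate `eta_m`; expectation
#' `v` tracks perceived reality `f*m + r` at learning rate `eta_v`. The mood
#' learning rate may differ between positive surprise (`eta_m_plus`) and
#' non-positive surprise (`eta_m_minus`), which splits the phase plane into
#' two half-planes along `v = f*m + r`.
#'
#' All rates are per week; mood is dimensionless and reality/expectation
#' share one arbitrary unit.
#'
#' @param eta_m_plus mood learning rate for positive surprise (1/week).
#' @param eta_v expectation learning rate (1/week).
#' @param f dimensionless scale of the mood contribution to perceived
#'   reality `f*m + r`.
#' @param k linear mood recovery rate (1/week).
#' @param k3 cubic mood recovery coefficient (1/(mood^2 week)).
#' @param eta_m_minus mood learning rate for non-positive surprise
#'   (1/week); defaults to `eta_m_plus` (the symmetric model).
#' @return An object of class `mood_params`.
#' @seealso [mood_params_from_ratios()] for the sensitivity-ratio
#'   parameterisation used throughout the analyses.
#' @examples
#' p <- mood_params(eta_m_plus = 3.7, eta_v = 0.37, f = 0.3, k = 0.37,
#'                  k3 = 2.8e-3)
#' is_symmetric(p)
#' @export
mood_params <- function(eta_m_plus, eta_v, f, k, k3, eta_m_minus = eta_m_plus) {
  vals <- c(eta_m_plus = eta_m_plus, eta_m_minus = eta_m_minus,
            eta_v = eta_v, f = f, k = k, k3 = k3)
  if (!is.numeric(vals) || length(vals) != 6L || any(!is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (any(vals <= 0))
    stop("all model parameters must be strictly positive; got non-positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  structure(as.list(vals), class = "mood_params")
}

#' Construct parameters from mood-sensitivity ratios
#'
#' The dynamics near the origin are controlled by the mood sensitivities
#' `f*eta_m_plus` and `f*eta_m_minus` relative to the critical value
#' `eta_v + k` (the Hopf threshold of the symmetric model). This helper
#' builds a parameter set with the requested sensitivity ratios, i.e.
#' `f*eta_m_pm = ratio_pm * (eta_v + k)`.
#'
#' @param ratio_plus,ratio_minus target values of
#'   `f*eta_m_pm / (eta_v + k)`; `ratio_minus` defaults to `ratio_plus`.
#' @inheritParams mood_params
#' @return A `mood_params` object.
#' @examples
#' # bipolar reference configuration: sensitivity 1.5x the critical value
#' mood_params_from_ratios(1.5, eta_v = 0.37, f = 0.3, k = 0.37, k3 = 2.8e-3)
#' @export
mood_params_from_ratios <- function(ratio_plus, eta_v, f, k, k3,
                                    ratio_minus = ratio_plus) {
  crit <- eta_v + k
  mood_params(eta_m_plus = ratio_plus * crit / f,
              eta_m_minus = ratio_minus * crit / f,
              eta_v = eta_v, f = f, k = k, k3 = k3)
}

#' @rdname mood_params
#' @param params a `mood_params` object.
#' @export
is_symmetric <- function(params) {
  stopifnot(inherits(params, "mood_params"))
  params$eta_m_plus == params$eta_m_minus
}

#' @export
print.mood_params <- function(x, ...) {
  crit <- x$eta_v + x$k
  cat("Mood-expectation model parameters (rates per week)\n")
  cat(sprintf("  eta_m+ = %g  eta_m- = %g  eta_v = %g\n",
              x$eta_m_plus, x$eta_m_minus, x$eta_v))
  cat(sprintf("  f = %g  k = %g  k3 = %g\n", x$f, x$k, x$k3))
  cat(sprintf("  mood sensitivities f*eta_m: + %.4g  - %.4g  (critical %.4g)\n",
              x$f * x$eta_m_plus, x$f * x$eta_m_minus, crit))
  invisible(x)
}

# mood sensitivity of one branch, f * eta_m
f_eta_m <- function(params, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  params$f * if (branch == "plus") params$eta_m_plus else params$eta_m_minus
}
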