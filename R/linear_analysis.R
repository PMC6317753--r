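#' Eigenvalues of the linearized dynamics
#'
#' Linearizing about the origin (constant reality 0, cubic term dropped)
#' gives the Jacobian `[[f*eta_m - k, -eta_m], [f*eta_v, -eta_v]]` with
#' eigenvalues
#' \deqn{\lambda_\pm = \tfrac{1}{2}(f\eta_m - \eta_v - k) \pm
#'       \tfrac{1}{2}\sqrt{\Delta}, \quad
#'       \Delta = (f\eta_m - \eta_v - k)^2 - 4\eta_v k.}
#' With asymmetric sensitivities each half-plane of `v = f*m` has its own
#' Jacobian; `branch` selects which learning rate is used.
#'
#' @param params a [mood_params()] object.
#' @param branch `"plus"` or `"minus"`, the learning-rate branch.
#' @return A list of class `eigen_report` with fields `lambda_plus`,
#'   `lambda_minus` (complex), `discriminant`, `trace`, `branch`.
#' @examples
#' p <- mood_params_from_ratios(1, eta_v = 0.37, f = 0.3, k = 0.37,
#'                              k3 = 2.8e-3)
#' eigen_report(p)  # at threshold: purely imaginary +- 0.37i
#' @export
eigen_report <- function(params, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  cf <- eigen_closed_form(f_eta_m(params, branch), params$eta_v, params$k)
  structure(c(cf, list(branch = branch)), class = "eigen_report")
}

#' @rdname eigen_report
#' @param f_eta_m mood sensitivity `f * eta_m` of the branch considered.
#' @param eta_v expectation learning rate.
#' @param k linear mood recovery rate; `k = 0` (no linear dissipation) is
#'   admitted here and makes the discriminant `(f_eta_m - eta_v)^2 >= 0`,
#'   so both eigenvalues are real and the damped-oscillation
#'   (cyclothymic) regime disappears.
#' @export
eigen_closed_form <- function(f_eta_m, eta_v, k) {
  stopifnot(f_eta_m > 0, eta_v > 0, k >= 0)
  tr <- f_eta_m - eta_v - k
  disc <- tr^2 - 4 * eta_v * k
  sq <- sqrt(as.complex(disc))
  list(lambda_plus = drop_zero_im((tr + sq) / 2),
       lambda_minus = drop_zero_im((tr - sq) / 2),
       discriminant = disc, trace = tr)
}

drop_zero_im <- function(z) if (Im(z) == 0) complex(real = Re(z), imaginary = 0) else z

#' @export
print.eigen_report <- function(x, ...) {
  cat(sprintf("eigenvalues (%s branch): %s, %s\n", x$branch,
              format(x$lambda_plus, digits = 6),
              format(x$lambda_minus, digits = 6)))
  cat(sprintf("  trace = %.6g  discriminant = %.6g\n", x$trace,
              x$discriminant))
  invisible(x)
}

#' Half-plane regime classification
#'
#' Classifies the linearized dynamics of one learning-rate branch by the
#' mood sensitivity `f*eta_m` relative to the critical value
#' `eta_v + k` and the spiral window of half-width `2*sqrt(eta_v*k)`:
#' stable node, stable spiral, unstable spiral, or unstable node.
#' Parameters within a relative tolerance of 1e-9 of a regime boundary
#' are reported as `"degenerate"` rather than silently classified.
#'
#' @inheritParams eigen_report
#' @return A character scalar, one of `"stable_node"`, `"stable_spiral"`,
#'   `"unstable_spiral"`, `"unstable_node"`, or `"degenerate"` (with a
#'   `"boundary"` attribute naming the boundary hit).
#' @export
classify_halfplane <- function(params, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  fe <- f_eta_m(params, branch)
  crit <- params$eta_v + params$k
  w <- 2 * sqrt(params$eta_v * params$k)
  tol <- 1e-9 * max(abs(fe), crit + w)
  bounds <- c(node_stable = crit - w, hopf = crit, node_unstable = crit + w)
  hit <- which(abs(fe - bounds) <= tol)
  if (length(hit))
    return(structure("degenerate", boundary = names(bounds)[hit[1L]]))
  if (fe < crit - w) "stable_node"
  else if (fe < crit) "stable_spiral"
  else if (fe < crit + w) "unstable_spiral"
  else "unstable_node"
}

#' Half-cycle growth factor of a spiral half-plane
#'
#' In a spiral half-plane, a linear trajectory entering on the boundary
#' `v = f*m` leaves it on the other side after the half-cycle time
#' `2*pi/sqrt(4*eta_v*k - tr^2)` with its distance to the origin
#' multiplied by
#' \deqn{\exp\!\left(\frac{\pi\,(f\eta_m - \eta_v - k)}
#'   {\sqrt{4\eta_v k - (f\eta_m - \eta_v - k)^2}}\right).}
#'
#' @inheritParams eigen_report
#' @return The positive multiplicative factor.
#' @export
half_cycle_multiplier <- function(params, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  regime <- classify_halfplane(params, branch)
  if (!regime %in% c("stable_spiral", "unstable_spiral"))
    stop("half-cycle multiplier is defined only for spiral half-planes ",
         "(got ", regime, ")")
  tr <- f_eta_m(params, branch) - params$eta_v - params$k
  exp(pi * tr / sqrt(4 * params$eta_v * params$k - tr^2))
}

# half-cycle residence time in a spiral half-plane
half_cycle_time <- function(params, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  tr <- f_eta_m(params, branch) - params$eta_v - params$k
  arg <- 4 * params$eta_v * params$k - tr^2
  if (arg <= 0) stop("half-cycle time defined only for spiral half-planes")
  2 * pi / sqrt(arg)
}

#' Spiral-spiral stability criterion
#'
#' When both half-planes are spirals, a full cycle multiplies the
#' distance to the origin by the product of the two half-cycle factors;
#' its log,
#' \deqn{\frac{\pi(f\eta_m^+ - \eta_v - k)}{\sqrt{4\eta_v k -
#'   (f\eta_m^+ - \eta_v - k)^2}} +
#'   \frac{\pi(f\eta_m^- - \eta_v - k)}{\sqrt{4\eta_v k -
#'   (f\eta_m^- - \eta_v - k)^2}},}
#' is negative exactly when the origin is linearly stable. The zero set
#' is `f*(eta_m_plus + eta_m_minus) = 2*(eta_v + k)`.
#'
#' @param params a [mood_params()] object whose two half-planes are both
#'   spirals.
#' @return The dimensionless criterion value (negative = stable).
#' @export
spiral_stability_criterion <- function(params) {
  term <- function(branch) {
    regime <- classify_halfplane(params, branch)
    if (!regime %in% c("stable_spiral", "unstable_spiral"))
      stop("the spiral-spiral criterion requires both half-planes to be ",
           "spirals (", branch, " branch is ", regime, ")")
    tr <- f_eta_m(params, branch) - params$eta_v - params$k
    pi * tr / sqrt(4 * params$eta_v * params$k - tr^2)
  }
  term("plus") + term("minus")
}

#' Predict linear stability of the origin
#'
#' Combines the two half-plane regimes into an overall verdict:
#' \itemize{
#'   \item both half-planes stable: stable; both unstable: unstable;
#'   \item a node coexisting with a spiral: the node's stability decides
#'     (most trajectories end up in, and stay in, the node half-plane);
#'   \item two spirals of opposite stability: the sign of [spiral_stability_criterion()]
#'     decides;
#'   \item stable node with unstable node: reported unstable (numerical
#'     solutions of the full model behave so), but flagged
#'     initial-condition-sensitive since no cycle argument applies and
#'     trajectories from some starting wedges behave differently.
#' }
#'
#' @param params a [mood_params()] object.
#' @return A list of class `stability_report`: `regime_plus`,
#'   `regime_minus`, `spiral_stability_criterion` (NA unless both half-planes are
#'   spirals), `verdict` (`"stable"`, `"unstable"`, or `"degenerate"`),
#'   `rule_used`, `initial_condition_sensitive`, and the two
#'   [eigen_report()]s.
#' @examples
#' p <- mood_params_from_ratios(0.4, eta_v = 1.48, f = 0.3, k = 0.37,
#'                              k3 = 2.8e-3)
#' predict_stability(p)$verdict
#' @export
predict_stability <- function(params) {
  rp <- classify_halfplane(params, "plus")
  rm <- classify_halfplane(params, "minus")
  e11 <- NA_real_
  ic_flag <- FALSE
  if (rp == "degenerate" || rm == "degenerate") {
    verdict <- "degenerate"; rule <- "boundary_parameters"
  } else {
    stable_p <- rp %in% c("stable_node", "stable_spiral")
    stable_m <- rm %in% c("stable_node", "stable_spiral")
    node_p <- rp %in% c("stable_node", "unstable_node")
    node_m <- rm %in% c("stable_node", "unstable_node")
    if (!node_p && !node_m)
      e11 <- spiral_stability_criterion(params)
    if (stable_p && stable_m) {
      verdict <- "stable"; rule <- "both_halfplanes_stable"
    } else if (!stable_p && !stable_m) {
      if (node_p && node_m) {
        verdict <- "unstable"; rule <- "both_halfplanes_unstable"
      } else {
        verdict <- "unstable"; rule <- "both_halfplanes_unstable"
      }
    } else if (node_p && node_m) {
      # one stable node, one unstable node: no half-cycle argument applies
      verdict <- "unstable"
      rule <- "node_node_conflict_numerically_unstable"
      ic_flag <- TRUE
    } else if (node_p || node_m) {
      node_stable <- if (node_p) stable_p else stable_m
      verdict <- if (node_stable) "stable" else "unstable"
      rule <- "node_dominates_spiral"
    } else {
      verdict <- if (e11 < 0) "stable" else "unstable"
      rule <- "spiral_spiral_full_cycle_multiplier"
    }
  }
  structure(list(regime_plus = rp, regime_minus = rm, spiral_stability_criterion = e11,
                 verdict = verdict, rule_used = rule,
                 initial_condition_sensitive = ic_flag,
                 eigen_plus = eigen_report(params, "plus"),
                 eigen_minus = eigen_report(params, "minus")),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("linear stability of the origin\n")
  cat(sprintf("  plus half-plane:  %s\n", x$regime_plus))
  cat(sprintf("  minus half-plane: %s\n", x$regime_minus))
  if (!is.na(x$spiral_stability_criterion))
    cat(sprintf("  spiral-spiral criterion value: %.6g\n", x$spiral_stability_criterion))
  cat(sprintf("  verdict: %s (%s)%s\n", x$verdict, x$rule_used,
              if (x$initial_condition_sensitive)
                " [initial-condition sensitive]" else ""))
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report a `stability_report`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
stability_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  fmt_eig <- function(e)
    list(lambda_plus = list(re = Re(e$lambda_plus), im = Im(e$lambda_plus)),
         lambda_minus = list(re = Re(e$lambda_minus), im = Im(e$lambda_minus)),
         discriminant = e$discriminant, trace = e$trace)
  obj <- list(regime_plus = report$regime_plus,
              regime_minus = report$regime_minus,
              spiral_stability_criterion = report$spiral_stability_criterion,
              verdict = report$verdict,
              rule_used = report$rule_used,
              initial_condition_sensitive = report$initial_condition_sensitive,
              eigenvalues = list(plus = fmt_eig(report$eigen_plus),
                                 minus = fmt_eig(report$eigen_minus)))
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
}
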