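#' Outer mood bound of the trapping rectangle
#'
#' For symmetric sensitivities and constant reality 0, the rectangle with
#' vertices `(+-m*, +-f*m*)` has the vector field pointing inward on its
#' edges, so it confines every trajectory that starts inside it and (with
#' an unstable origin) forces a limit cycle. The bound is the positive
#' root of the mood-nullcline intersection,
#' \deqn{m^* = \sqrt{(2 f \eta_m - k)/k_3}.}
#'
#' @param params a symmetric [mood_params()] object with
#'   `2*f*eta_m >= k`.
#' @return The bound `m*` (mood units).
#' @examples
#' p <- mood_params_from_ratios(1.5, eta_v = 0.37, f = 0.3, k = 0.37,
#'                              k3 = 2.8e-3)
#' m_star(p)  # about 25.7
#' @export
m_star <- function(params) {
  if (!is_symmetric(params))
    stop("the outer bound is defined for symmetric mood sensitivities")
  num <- 2 * f_eta_m(params, "plus") - params$k
  if (num < 0)
    stop("no positive nullcline root: need 2*f*eta_m >= k")
  sqrt(num / params$k3)
}

#' Summarise the oscillation of a trajectory
#'
#' Discards the transient, detects mood extrema on the dense output by
#' sign changes of the discrete derivative (with quadratic refinement),
#' and reports the mean absolute extremal mood (amplitude), the mean
#' interval between successive maxima (period), and the standard
#' deviation of mood over the assessment window -- the variability
#' statistic used by the stability scans. The cycle is flagged converged
#' when the last few maxima agree in amplitude to better than 1%.
#'
#' @param traj a `mood_trajectory`.
#' @param assessment_fraction fraction of the horizon (from the end) used
#'   for assessment; the default 0.5 assesses the second half.
#' @return A list of class `limit_cycle_summary`: `amplitude`, `period`,
#'   `mood_sd`, `converged`, `n_peaks`, and `m_star` (NA; filled by
#'   [amplitude_scan()]).
#' @export
estimate_cycle <- function(traj, assessment_fraction = 0.5) {
  stopifnot(assessment_fraction > 0, assessment_fraction <= 1)
  t_end <- traj$time[nrow(traj)]
  t_start <- t_end - assessment_fraction * (t_end - traj$time[1L])
  win <- traj$time >= t_start
  tt <- traj$time[win]; m <- traj$m[win]
  n <- length(m)
  mood_sd <- stats::sd(m)

  res <- list(amplitude = 0, period = NA_real_, mood_sd = mood_sd,
              converged = FALSE, n_peaks = 0L, m_star = NA_real_)
  class(res) <- "limit_cycle_summary"
  if (n < 5L) return(res)

  dm <- diff(m)
  sign_change <- which(dm[-length(dm)] > 0 & dm[-1L] <= 0)  # maxima
  sign_change_min <- which(dm[-length(dm)] < 0 & dm[-1L] >= 0)  # minima
  max_idx <- sign_change + 1L
  min_idx <- sign_change_min + 1L
  refine <- function(i) refine_peak(tt[(i - 1L):(i + 1L)], m[(i - 1L):(i + 1L)])
  maxima <- lapply(max_idx[max_idx > 1L & max_idx < n], refine)
  minima <- lapply(min_idx[min_idx > 1L & min_idx < n], refine)
  if (length(maxima) < 3L) return(res)

  max_t <- vapply(maxima, `[[`, numeric(1), "t")
  max_y <- vapply(maxima, `[[`, numeric(1), "y")
  min_y <- vapply(minima, `[[`, numeric(1), "y")
  res$n_peaks <- length(max_y) + length(min_y)
  res$amplitude <- mean(abs(c(max_y, min_y)))
  res$period <- mean(diff(max_t))
  last <- utils::tail(abs(max_y), 5L)
  res$converged <- length(last) >= 3L &&
    (max(last) - min(last)) < 0.01 * mean(last)
  res
}

#' @export
print.limit_cycle_summary <- function(x, ...) {
  cat(sprintf(
    "limit cycle: amplitude %.4g, period %.4g weeks, mood sd %.4g (%s)\n",
    x$amplitude, x$period, x$mood_sd,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Hopf threshold of the symmetric model
#'
#' The origin loses stability, and a limit cycle is born, when the mood
#' sensitivity `f*eta_m` crosses `eta_v + k`. With `verify = TRUE` the
#' analytic threshold is cross-checked by bisection on simulated
#' long-run behaviour: at each candidate sensitivity the system is
#' started near the origin and classified as growing or decaying by
#' comparing the mood envelope in the last quarter of the run with the
#' quarter before it.
#'
#' @param params a symmetric [mood_params()] object (its `eta_m` is the
#'   free parameter and is ignored; `eta_v` and `k` set the threshold).
#' @param verify if `TRUE`, also return a simulation-based bisection
#'   estimate.
#' @param bracket initial sensitivity bracket for the bisection, as
#'   multiples of the analytic threshold.
#' @param horizon simulation length per bisection step (weeks).
#' @param tol_rel relative width at which the bisection stops.
#' @return The analytic threshold `eta_v + k`; with `verify = TRUE`, a
#'   list with `analytic` and `bisection` values.
#' @export
hopf_threshold <- function(params, verify = FALSE, bracket = c(0.8, 1.2),
                           horizon = 900, tol_rel = 0.004) {
  crit <- params$eta_v + params$k
  if (!verify) return(crit)
  grows <- function(fe) {
    p <- mood_params(eta_m_plus = fe / params$f, eta_v = params$eta_v,
                     f = params$f, k = params$k, k3 = params$k3)
    traj <- simulate_mood(p, constant_reality(0, horizon),
                          init = c(0, -0.05), horizon = horizon,
                          opts = solver_options(rel_tol = 1e-9,
                                                abs_tol = 1e-12,
                                                grid_dt = 0.25))
    n <- nrow(traj)
    q4 <- stats::sd(traj$m[(3 * n %/% 4):n])
    q3 <- stats::sd(traj$m[(n %/% 2):(3 * n %/% 4)])
    # growing envelope, or already saturated on a macroscopic cycle
    # (far above the 0.05 starting amplitude)
    q4 > q3 || q4 > 0.5
  }
  lo <- bracket[1L] * crit; hi <- bracket[2L] * crit
  if (grows(lo) || !grows(hi))
    stop("bisection bracket does not straddle the oscillation onset")
  while ((hi - lo) > tol_rel * crit) {
    mid <- (lo + hi) / 2
    if (grows(mid)) hi <- mid else lo <- mid
  }
  list(analytic = crit, bisection = (lo + hi) / 2)
}

#' Amplitude versus mood sensitivity
#'
#' Simulates the symmetric model at each requested sensitivity, extracts
#' the converged cycle amplitude, and tabulates it against the outer
#' bound `m*`. Far above threshold the bound captures the square-root
#' growth of the amplitude in `f*eta_m`.
#'
#' @param params a symmetric [mood_params()] template (`eta_v`, `f`, `k`,
#'   `k3` are used; `eta_m` is set per scan point).
#' @param f_eta_m_values supra-threshold mood sensitivities to scan.
#' @param horizon simulation length per point (weeks).
#' @param init initial state.
#' @param opts [solver_options()].
#' @return A data frame with columns `f_eta_m`, `amplitude`, `period`,
#'   `m_star`, `converged`.
#' @export
amplitude_scan <- function(params, f_eta_m_values, horizon = 300,
                           init = c(0, -1),
                           opts = solver_options(rel_tol = 1e-8,
                                                 abs_tol = 1e-10,
                                                 grid_dt = 0.05)) {
  crit <- params$eta_v + params$k
  if (any(f_eta_m_values <= crit))
    stop("amplitude_scan requires supra-threshold sensitivities ",
         "(f*eta_m > eta_v + k)")
  rows <- lapply(f_eta_m_values, function(fe) {
    p <- mood_params(eta_m_plus = fe / params$f, eta_v = params$eta_v,
                     f = params$f, k = params$k, k3 = params$k3)
    traj <- simulate_mood(p, constant_reality(0, horizon), init = init,
                          horizon = horizon, opts = opts)
    cyc <- estimate_cycle(traj)
    data.frame(f_eta_m = fe, amplitude = cyc$amplitude,
               period = cyc$period, m_star = m_star(p),
               converged = cyc$converged)
  })
  do.call(rbind, rows)
}

#' Two-parameter stability scan
#'
#' Reproduces the stability map in the `(f*eta_m_plus, f*eta_m_minus)`
#' plane: each grid cell is simulated under constant reality 0 and its
#' mood standard deviation over the assessment window is compared with
#' the variability of the critical model
#' (`f*eta_m_plus = f*eta_m_minus = eta_v + k`) run under the identical
#' protocol, which serves as the empirical stable/unstable contour
#' level. The analytic [predict_stability()] verdict is attached per
#' cell.
#'
#' @param eta_v,f,k,k3 shared model constants.
#' @param ratios_plus,ratios_minus grids of sensitivity ratios
#'   `f*eta_m_pm / (eta_v + k)`.
#' @param horizon simulation length (weeks); the classic protocol uses
#'   162.5 with the second half assessed.
#' @param init initial state for every cell.
#' @param opts [solver_options()]; scans default to moderately relaxed
#'   tolerances and a coarser grid for throughput.
#' @param assessment_fraction window passed to [estimate_cycle()].
#' @return A data frame of class `scan_result` in long format with
#'   columns `ratio_plus`, `ratio_minus`, `f_eta_m_plus`,
#'   `f_eta_m_minus`, `mood_sd`, `empirical_call`, `analytic_verdict`,
#'   `regime_plus`, `regime_minus`, `failed`; the contour level and
#'   protocol are kept as attributes.
#' @export
stability_scan <- function(eta_v, f, k, k3, ratios_plus, ratios_minus,
                           horizon = 162.5, init = c(0, -1),
                           opts = solver_options(rel_tol = 1e-6,
                                                 abs_tol = 1e-8,
                                                 grid_dt = 0.25),
                           assessment_fraction = 0.5) {
  crit <- eta_v + k
  run_sd <- function(rp, rm) {
    p <- mood_params_from_ratios(rp, eta_v = eta_v, f = f, k = k, k3 = k3,
                                 ratio_minus = rm)
    traj <- simulate_mood(p, constant_reality(0, horizon), init = init,
                          horizon = horizon, opts = opts)
    estimate_cycle(traj, assessment_fraction)$mood_sd
  }
  contour <- run_sd(1, 1)

  cells <- expand.grid(ratio_plus = ratios_plus, ratio_minus = ratios_minus,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    rp <- cells$ratio_plus[i]; rm <- cells$ratio_minus[i]
    p <- mood_params_from_ratios(rp, eta_v = eta_v, f = f, k = k, k3 = k3,
                                 ratio_minus = rm)
    sdv <- tryCatch(run_sd(rp, rm), error = function(e) NA_real_)
    rep_ <- predict_stability(p)
    data.frame(ratio_plus = rp, ratio_minus = rm,
               f_eta_m_plus = rp * crit, f_eta_m_minus = rm * crit,
               mood_sd = sdv,
               empirical_call = if (is.na(sdv)) NA_character_
                 else if (sdv > contour) "unstable" else "stable",
               analytic_verdict = rep_$verdict,
               regime_plus = rep_$regime_plus,
               regime_minus = rep_$regime_minus,
               failed = is.na(sdv))
  })
  out <- do.call(rbind, res)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "contour_level") <- contour
  attr(out, "protocol") <- list(eta_v = eta_v, f = f, k = k, k3 = k3,
                                horizon = horizon, init = init,
                                assessment_fraction = assessment_fraction)
  out
}

#' Agreement between analytic and empirical stability calls
#'
#' Summarises a [stability_scan()]: the fraction of cells where the
#' analytic verdict matches the empirical (mood-variability) call.
#' Cells adjacent to an analytic verdict change ("boundary band") can be
#' excluded, since the finite-horizon variability statistic cannot
#' resolve the boundary to better than one cell.
#'
#' @param scan a `scan_result`.
#' @param exclude_boundary drop cells whose 4-neighbourhood contains a
#'   differing analytic verdict.
#' @param spiral_only restrict to cells where both half-planes are
#'   spirals.
#' @return A list with `agreement`, `n_cells`, `n_agree`.
#' @export
scan_agreement <- function(scan, exclude_boundary = TRUE,
                           spiral_only = FALSE) {
  stopifnot(inherits(scan, "scan_result"))
  rp <- sort(unique(scan$ratio_plus)); rm <- sort(unique(scan$ratio_minus))
  key <- function(a, b) paste(sprintf("%.12g", a), sprintf("%.12g", b))
  verdict <- stats::setNames(scan$analytic_verdict,
                             key(scan$ratio_plus, scan$ratio_minus))
  keep <- rep(TRUE, nrow(scan))
  if (spiral_only)
    keep <- keep & scan$regime_plus %in% c("stable_spiral", "unstable_spiral") &
      scan$regime_minus %in% c("stable_spiral", "unstable_spiral")
  if (exclude_boundary) {
    for (i in seq_len(nrow(scan))) {
      ip <- match(scan$ratio_plus[i], rp); im <- match(scan$ratio_minus[i], rm)
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        jp <- ip + d[1L]; jm <- im + d[2L]
        if (jp < 1L || jp > length(rp) || jm < 1L || jm > length(rm)) next
        nb <- verdict[[key(rp[jp], rm[jm])]]
        if (!identical(nb, scan$analytic_verdict[i])) { keep[i] <- FALSE; break }
      }
    }
  }
  keep <- keep & !scan$failed & !is.na(scan$empirical_call) &
    scan$analytic_verdict %in% c("stable", "unstable")
  agree <- scan$empirical_call[keep] == scan$analytic_verdict[keep]
  list(agreement = mean(agree), n_cells = sum(keep), n_agree = sum(agree))
}
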