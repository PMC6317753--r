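#' Solver options
#'
#' @param rel_tol,abs_tol relative/absolute integration tolerances.
#' @param max_step maximum internal step size (weeks); `Inf` leaves the
#'   choice to the solver.
#' @param grid_dt spacing of the output grid (weeks). The default 0.05
#'   resolves oscillation periods of tens of weeks with thousands of
#'   samples per cycle.
#' @param smooth_width optional logistic smoothing width (reality units)
#'   for the learning-rate switch; 0 (default) keeps the exact
#'   Heaviside switch with event-located branch changes.
#' @param max_switches guard against event chattering: maximum number of
#'   branch switches per simulation.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = Inf,
                           grid_dt = 0.05, smooth_width = 0,
                           max_switches = 100000L) {
  stopifnot(rel_tol > 0, abs_tol > 0, grid_dt > 0, smooth_width >= 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 grid_dt = grid_dt, smooth_width = smooth_width,
                 max_switches = as.integer(max_switches)),
            class = "solver_options")
}

# derivative field with a fixed learning-rate branch (smooth in each
# half-plane, so the solver never steps across a derivative discontinuity)
make_rhs <- function(params, eta, r_of_t, linearized) {
  k <- params$k; k3 <- if (linearized) 0 else params$k3
  f <- params$f; eta_v <- params$eta_v
  function(t, y, parms) {
    s <- f * y[1L] + r_of_t(t) - y[2L]
    list(c(eta * s - k * y[1L] - k3 * y[1L]^3, eta_v * s))
  }
}

make_rootfunc <- function(params, r_of_t) {
  f <- params$f
  function(t, y, parms) f * y[1L] + r_of_t(t) - y[2L]
}

# branch after touching the switching surface: the sign of ds/dt there.
# On the surface the surprise vanishes, so dm = -km - k3 m^3, dv = 0 and
# ds/dt = f*dm + dr; drift <= 0 goes to (or stays on) the minus branch,
# matching the boundary convention of the Heaviside switch.
branch_from_drift <- function(m, params, linearized, dr = 0) {
  dm <- -params$k * m - (if (linearized) 0 else params$k3) * m^3
  drift <- params$f * dm + dr
  if (drift > 0) "plus" else "minus"
}

active_branch <- function(m, v, r, params, linearized, dr = 0) {
  s <- params$f * m + r - v
  edge <- 1e-12 * (1 + abs(v) + abs(r))
  if (s > edge) "plus"
  else if (s < -edge) "minus"
  else branch_from_drift(m, params, linearized, dr)
}

# numeric dr/dt for functional reality (piecewise-constant reality has
# dr = 0 inside a segment)
dr_of <- function(reality, t) {
  if (!is.function(reality)) return(0)
  h <- 1e-6
  (reality(t + h) - reality(t - h)) / (2 * h)
}

#' Simulate the mood-expectation system
#'
#' Integrates the piecewise-smooth system with deSolve's `lsodar`. When
#' the mood sensitivities are asymmetric, a root-finding event locates
#' every crossing of the switching surface `f*m + r - v = 0` and the
#' integration restarts with the learning-rate branch selected by the
#' crossing direction, so the solver never steps across the derivative
#' discontinuity. Reality jumps and intervention times are hard
#' integration breakpoints; the state is continuous across them.
#'
#' @param params a [mood_params()] object.
#' @param reality a [reality] object (piecewise-constant), a plain
#'   function of time (smooth reality), or a single number (constant).
#' @param init initial state, `c(m, v)`.
#' @param horizon end time in weeks; defaults to the reality horizon.
#' @param opts a [solver_options()] list.
#' @param interventions an optional [intervention_schedule()].
#' @param linearized if `TRUE`, drop the cubic recovery term and
#'   integrate the piecewise-linear system (used by the half-plane
#'   stability analysis).
#' @return A data frame of class `mood_trajectory` with columns
#'   `time, m, v, r, branch` (`branch` is +1/-1 for the active
#'   learning-rate branch), and attributes `event_log` (data frame of
#'   switch crossings, reality jumps and interventions), `params`
#'   (parameters in force at the end), and `opts`.
#' @examples
#' p <- mood_params_from_ratios(0.3, eta_v = 0.37, f = 0.3, k = 0.37,
#'                              k3 = 2.8e-3)
#' traj <- simulate_mood(p, constant_reality(0, 150), init = c(0, -1))
#' tail(traj$m, 1)  # damped below threshold: mood relaxes to 0
#' @export
simulate_mood <- function(params, reality, init = c(0, 0), horizon = NULL,
                          opts = solver_options(), interventions = NULL,
                          linearized = FALSE) {
  stopifnot(inherits(params, "mood_params"))
  if (is.numeric(reality) && length(reality) == 1L) {
    if (is.null(horizon)) stop("horizon required with a scalar reality")
    reality <- constant_reality(reality, horizon)
  }
  if (is.null(horizon)) {
    if (is.function(reality)) stop("horizon required with a functional reality")
    horizon <- reality$horizon
  }
  init <- as.numeric(init)
  if (length(init) != 2L || any(!is.finite(init)))
    stop("init must be a finite vector c(m, v)")
  stopifnot(horizon > 0)

  grid <- seq(0, horizon, by = opts$grid_dt)
  if (horizon - grid[length(grid)] > 1e-9 * max(1, opts$grid_dt))
    grid <- c(grid, horizon)
  else grid[length(grid)] <- horizon
  n_grid <- length(grid)
  out_m <- rep(NA_real_, n_grid); out_v <- rep(NA_real_, n_grid)
  out_r <- rep(NA_real_, n_grid)

  iv_times <- numeric(0)
  if (!is.null(interventions)) {
    stopifnot(inherits(interventions, "intervention_schedule"))
    iv <- interventions[order(interventions$time), , drop = FALSE]
    if (any(iv$time <= 0 | iv$time >= horizon))
      stop("intervention times must lie strictly inside (0, horizon)")
    iv_times <- iv$time
  }

  breaks <- sort(unique(c(0, reality_breakpoints(reality, 0, horizon),
                          iv_times, horizon)))
  events <- list()
  log_event <- function(time, type, detail)
    events[[length(events) + 1L]] <<- data.frame(time = time, type = type,
                                                 detail = detail)
  cur_params <- params
  y <- init
  running_min_m <- init[1L]
  n_switches <- 0L

  store_rows <- function(times, states, r_vals) {
    idx <- round((times - grid[1L]) / opts$grid_dt) + 1L
    idx[idx < 1L] <- 1L
    idx[idx > n_grid] <- n_grid
    ok <- abs(grid[idx] - times) < 1e-9
    idx <- idx[ok]
    out_m[idx] <<- states[ok, 1L]; out_v[idx] <<- states[ok, 2L]
    out_r[idx] <<- r_vals[ok]
  }

  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]

    # apply any intervention scheduled at this breakpoint
    if (!is.null(interventions) && any(abs(iv_times - t0) < 1e-12)) {
      for (j in which(abs(iv$time - t0) < 1e-12)) {
        applied <- apply_intervention(iv$kind[j], iv$magnitude[j],
                                      y, running_min_m, cur_params)
        y <- applied$state; cur_params <- applied$params
        log_event(t0, "intervention",
                  sprintf("%s magnitude=%g", iv$kind[j], iv$magnitude[j]))
      }
    }
    if (inherits(reality, "reality") && t0 > 0 &&
        any(abs(reality$jump_times - t0) < 1e-12))
      log_event(t0, "reality_jump",
                sprintf("r -> %g", reality_at(reality, t0)))

    if (is.function(reality)) {
      r_of_t <- reality
      r_const <- NA_real_
    } else {
      r_const <- reality_at(reality, t0)
      r_of_t <- function(t) r_const
    }
    use_roots <- !is_symmetric(cur_params) && opts$smooth_width == 0

    t_cur <- t0
    repeat {
      branch <- active_branch(y[1L], y[2L], r_of_t(t_cur), cur_params,
                              linearized, dr_of(reality, t_cur))
      if (opts$smooth_width > 0) {
        # logistic blend of the two learning rates; smooth field, no events
        p <- cur_params; w <- opts$smooth_width
        rhs <- local({
          pp <- p
          function(t, yy, parms) {
            s <- pp$f * yy[1L] + r_of_t(t) - yy[2L]
            eta <- pp$eta_m_minus +
              (pp$eta_m_plus - pp$eta_m_minus) * stats::plogis(s / w)
            k3 <- if (linearized) 0 else pp$k3
            list(c(eta * s - pp$k * yy[1L] - k3 * yy[1L]^3,
                   pp$eta_v * s))
          }
        })
      } else {
        eta <- if (branch == "plus") cur_params$eta_m_plus else cur_params$eta_m_minus
        rhs <- make_rhs(cur_params, eta, r_of_t, linearized)
      }

      tseq <- unique(c(t_cur, grid[grid > t_cur + 1e-12 & grid < t1 - 1e-12], t1))
      sol <- deSolve::lsodar(
        y = y, times = tseq, func = rhs, parms = NULL,
        rtol = opts$rel_tol, atol = opts$abs_tol,
        hmax = if (is.finite(opts$max_step)) opts$max_step else NULL,
        rootfunc = if (use_roots && opts$smooth_width == 0)
          make_rootfunc(cur_params, r_of_t) else NULL)
      istate <- attr(sol, "istate")
      if (any(!is.finite(sol)))
        stop(sprintf("integration diverged near t = %.4g weeks", t_cur))
      last_t <- sol[nrow(sol), 1L]
      states <- sol[, 2:3, drop = FALSE]
      store_rows(sol[, 1L], states,
                 if (is.function(reality)) reality(sol[, 1L])
                 else rep(r_const, nrow(sol)))
      running_min_m <- min(running_min_m, states[, 1L])
      y <- as.numeric(states[nrow(states), ])
      if (abs(y[1L]) > 1e8)
        stop(sprintf("integration diverged (|m| > 1e8) near t = %.4g weeks", last_t))

      root_hit <- !is.null(istate) && istate[1L] == 3 && last_t < t1 - 1e-12
      if (!root_hit) {
        if (last_t < t1 - 1e-9)
          stop(sprintf("integrator stopped early at t = %.6g weeks", last_t))
        break
      }
      # branch switch located: restart on the side selected by the drift
      n_switches <- n_switches + 1L
      if (n_switches > opts$max_switches)
        stop("too many switching events (chattering); consider a nonzero ",
             "smooth_width in solver_options()")
      new_branch <- branch_from_drift(y[1L], cur_params, linearized,
                                      dr_of(reality, last_t))
      log_event(last_t, "branch_switch", sprintf("to %s", new_branch))
      # tiny fixed step with the new branch moves the state off the surface
      h <- min(1e-9, (t1 - last_t) / 2)
      eta2 <- if (new_branch == "plus") cur_params$eta_m_plus else cur_params$eta_m_minus
      rhs2 <- make_rhs(cur_params, eta2, r_of_t, linearized)
      y <- rk4_step(rhs2, last_t, y, h)
      t_cur <- last_t + h
      if (t_cur >= t1 - 1e-12) break
    }
  }

  # segment tiling guarantees every grid point was written
  stopifnot(!anyNA(out_m))
  s <- params_surprise_series(out_m, out_v, out_r, cur_params)
  traj <- data.frame(time = grid, m = out_m, v = out_v, r = out_r,
                     branch = ifelse(s > 0, 1L, -1L))
  class(traj) <- c("mood_trajectory", "data.frame")
  attr(traj, "event_log") <- if (length(events)) do.call(rbind, events)
    else data.frame(time = numeric(0), type = character(0),
                    detail = character(0))
  attr(traj, "params") <- cur_params
  attr(traj, "opts") <- opts
  attr(traj, "linearized") <- linearized
  traj
}

params_surprise_series <- function(m, v, r, params) params$f * m + r - v

rk4_step <- function(rhs, t, y, h) {
  k1 <- rhs(t, y, NULL)[[1L]]
  k2 <- rhs(t + h / 2, y + h / 2 * k1, NULL)[[1L]]
  k3 <- rhs(t + h / 2, y + h / 2 * k2, NULL)[[1L]]
  k4 <- rhs(t + h, y + h * k3, NULL)[[1L]]
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate the piecewise-linear system
#'
#' Drops the cubic recovery term and integrates the linearization about
#' the origin under constant reality 0, retaining the learning-rate
#' switch. This is the system whose half-plane solutions underlie the
#' closed-form stability criteria; see [half_cycle_multiplier()] and
#' [spiral_stability_criterion()].
#'
#' @inheritParams simulate_mood
#' @export
simulate_linearized <- function(params, init, horizon,
                                opts = solver_options()) {
  simulate_mood(params, constant_reality(0, horizon), init = init,
                horizon = horizon, opts = opts, linearized = TRUE)
}

#' Integrate the second-order (Lienard) mood equation
#'
#' Integrates [lienard_rhs()] as a first-order system in `(m, dm/dt)`,
#' for cross-checking the equivalence of the second-order form with the
#' first-order system under smooth reality.
#'
#' @param params symmetric [mood_params()].
#' @param m0,dm0 initial mood and mood velocity. For consistency with a
#'   first-order initial state `(m0, v0)`, take
#'   `dm0 = eta_m*(f*m0 + r(0) - v0) - k*m0 - k3*m0^3`.
#' @param r_fun,dr_fun reality and its time derivative, as functions.
#' @param horizon end time (weeks).
#' @param opts [solver_options()].
#' @return Data frame with columns `time, m, dm`.
#' @export
simulate_lienard <- function(params, m0, dm0, r_fun, dr_fun, horizon,
                             opts = solver_options()) {
  if (!is_symmetric(params))
    stop("the Lienard form requires symmetric mood sensitivities")
  rhs <- function(t, y, parms) {
    list(c(y[2L], lienard_rhs(y[1L], y[2L], dr_fun(t), params)))
  }
  tseq <- seq(0, horizon, by = opts$grid_dt)
  if (tseq[length(tseq)] < horizon) tseq <- c(tseq, horizon)
  sol <- deSolve::lsoda(c(m0, dm0), tseq, rhs, parms = NULL,
                        rtol = opts$rel_tol, atol = opts$abs_tol)
  data.frame(time = sol[, 1L], m = sol[, 2L], dm = sol[, 3L])
}

#' @export
print.mood_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("mood trajectory: %d samples on [%g, %g] weeks\n",
              n, x$time[1L], x$time[n]))
  cat(sprintf("  final state m = %.4g, v = %.4g; %d logged event(s)\n",
              x$m[n], x$v[n], nrow(attr(x, "event_log"))))
  invisible(x)
}
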