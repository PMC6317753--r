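#' QIDS-SR16 depression score of a trajectory
#'
#' Maps mood to a Quick Inventory of Depressive Symptomatology score by
#' rectifying negative mood: `score(t) = min(clip_max, scale * max(0, -m(t)))`.
#' Positive or zero mood scores 0; the instrument's range caps the score
#' at 27 by default. The scale factor maps the model's arbitrary mood
#' unit onto QIDS points.
#'
#' @param traj a `mood_trajectory` (or any data frame with an `m` column).
#' @param scale positive mood-to-QIDS conversion factor.
#' @param clip_max score ceiling; `Inf` disables clipping.
#' @return Numeric vector of scores, one per trajectory sample.
#' @examples
#' qids_from_mood <- function(m) pmin(27, pmax(0, -m))
#' qids_from_mood(c(3, -2))  # 0 for positive mood, 2 for mood -2
#' @export
qids_series <- function(traj, scale = 1, clip_max = 27) {
  stopifnot(is.numeric(scale), scale > 0)
  pmin(clip_max, scale * pmax(0, -traj$m))
}

#' Medication intervention schedules
#'
#' Interventions modify the running simulation at scheduled times:
#' \describe{
#'   \item{`mood_shift_fraction`}{antidepressant modelled as a mood
#'     elevation: mood is reset to `magnitude` times the lowest mood
#'     attained so far (a dose fraction `p` in (0,1); smaller `p` is a
#'     larger dose). Expectation is unchanged.}
#'   \item{`set_positive_sensitivity`}{antidepressant modelled as an
#'     increased sensitivity to positive surprise: from the event time
#'     on, `eta_m_plus` is replaced so that `f*eta_m_plus` equals
#'     `magnitude`.}
#'   \item{`scale_both_sensitivities`}{lithium-like sedation: both
#'     learning rates are multiplied by `magnitude` (e.g. 0.8 for a
#'     symmetric 20% sensitivity reduction).}
#' }
#'
#' @param ... intervention events created by [intervention()] or the
#'   convenience wrappers below.
#' @return A data frame of class `intervention_schedule` with columns
#'   `time`, `kind`, `magnitude`, ordered by time.
#' @examples
#' sched <- intervention_schedule(antidepressant_mood_shift(9.2, p = 0.3))
#' @export
intervention_schedule <- function(...) {
  evs <- list(...)
  if (length(evs) == 1L && is.data.frame(evs[[1L]])) evs <- list(evs[[1L]])
  df <- do.call(rbind, evs)
  stopifnot(all(c("time", "kind", "magnitude") %in% names(df)))
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("intervention_schedule", "data.frame")
  df
}

#' @rdname intervention_schedule
#' @param time event time (weeks, strictly inside the simulation window).
#' @param kind one of `"mood_shift_fraction"`, `"set_positive_sensitivity"`,
#'   `"scale_both_sensitivities"`.
#' @param magnitude event magnitude; interpretation depends on `kind`.
#' @export
intervention <- function(time, kind = c("mood_shift_fraction",
                                        "set_positive_sensitivity",
                                        "scale_both_sensitivities"),
                         magnitude) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time),
            is.numeric(magnitude), length(magnitude) == 1L,
            is.finite(magnitude))
  if (kind == "mood_shift_fraction" && (magnitude <= 0 || magnitude >= 1))
    stop("mood_shift_fraction requires a dose fraction p in (0, 1)")
  if (kind != "mood_shift_fraction" && magnitude <= 0)
    stop("sensitivity magnitudes must be positive")
  data.frame(time = time, kind = kind, magnitude = magnitude)
}

#' @rdname intervention_schedule
#' @param p dose fraction in (0,1): mood is reset to `p` times its lowest
#'   value so far (smaller `p` = stronger dose).
#' @export
antidepressant_mood_shift <- function(time, p)
  intervention(time, "mood_shift_fraction", p)

#' @rdname intervention_schedule
#' @param f_eta_m_plus new positive mood sensitivity (value of
#'   `f*eta_m_plus` from the event time on).
#' @export
antidepressant_sensitivity <- function(time, f_eta_m_plus)
  intervention(time, "set_positive_sensitivity", f_eta_m_plus)

#' @rdname intervention_schedule
#' @param fraction sensitivity reduction in (0,1); both learning rates are
#'   scaled by `1 - fraction`.
#' @export
lithium_reduction <- function(time, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  intervention(time, "scale_both_sensitivities", 1 - fraction)
}

# applied by the integrator at a breakpoint; returns modified state/params
apply_intervention <- function(kind, magnitude, state, running_min_m, params) {
  if (kind == "mood_shift_fraction") {
    if (state[1L] >= 0)
      warning("antidepressant mood shift applied outside a depressive ",
              "episode (m >= 0)")
    state[1L] <- magnitude * running_min_m
  } else if (kind == "set_positive_sensitivity") {
    params <- mood_params(eta_m_plus = magnitude / params$f,
                          eta_v = params$eta_v, f = params$f,
                          k = params$k, k3 = params$k3,
                          eta_m_minus = params$eta_m_minus)
  } else if (kind == "scale_both_sensitivities") {
    params <- mood_params(eta_m_plus = params$eta_m_plus * magnitude,
                          eta_v = params$eta_v, f = params$f,
                          k = params$k, k3 = params$k3,
                          eta_m_minus = params$eta_m_minus * magnitude)
  } else stop("unknown intervention kind: ", kind)
  list(state = state, params = params)
}

#' Episode timing summaries of a trajectory
#'
#' Helpers for dose-response analyses: the time and height of the first
#' mood maximum (first manic peak) and the first QIDS peak after a given
#' time.
#'
#' @param traj a `mood_trajectory`.
#' @param after only consider samples at `time > after` (weeks).
#' @param min_height ignore maxima below this mood level.
#' @return `first_mood_peak()`: a list with `time` and `m`;
#'   `first_qids_peak()`: a list with `time` and `score`.
#' @export
first_mood_peak <- function(traj, after = 0, min_height = 0) {
  idx <- which(traj$time > after)
  m <- traj$m[idx]; tt <- traj$time[idx]
  n <- length(m)
  if (n < 3L) return(list(time = NA_real_, m = NA_real_))
  pk <- which(m[2:(n - 1L)] >= m[1:(n - 2L)] & m[2:(n - 1L)] > m[3:n]) + 1L
  pk <- pk[m[pk] > min_height]
  if (!length(pk)) return(list(time = NA_real_, m = NA_real_))
  i <- pk[1L]
  ref <- refine_peak(tt[(i - 1L):(i + 1L)], m[(i - 1L):(i + 1L)])
  list(time = ref$t, m = ref$y)
}

#' @rdname first_mood_peak
#' @param scale,clip_max passed to [qids_series()].
#' @export
first_qids_peak <- function(traj, after = 0, scale = 1, clip_max = 27) {
  q <- qids_series(traj, scale = scale, clip_max = clip_max)
  idx <- which(traj$time > after)
  qq <- q[idx]; tt <- traj$time[idx]
  n <- length(qq)
  if (n < 3L) return(list(time = NA_real_, score = NA_real_))
  pk <- which(qq[2:(n - 1L)] >= qq[1:(n - 2L)] & qq[2:(n - 1L)] > qq[3:n]) + 1L
  pk <- pk[qq[pk] > 0]
  if (!length(pk)) return(list(time = NA_real_, score = NA_real_))
  i <- pk[1L]
  list(time = tt[i], score = qq[i])
}

# Extremum through three equally spaced samples: the time is refined by
# the parabolic vertex, the value is taken from the central sample. On
# the dense output grid the sample value is accurate to O((dt/T)^2)
# relative, whereas a parabolic value overshoots on the steep asymmetric
# peaks of relaxation oscillations.
refine_peak <- function(t3, y3) {
  dt1 <- t3[2L] - t3[1L]; dt2 <- t3[3L] - t3[2L]
  denom <- y3[1L] - 2 * y3[2L] + y3[3L]
  if (abs(denom) < 1e-300 || abs(dt1 - dt2) > 1e-9 * max(dt1, dt2))
    return(list(t = t3[2L], y = y3[2L]))
  delta <- max(-1, min(1, 0.5 * (y3[1L] - y3[3L]) / denom))
  list(t = t3[2L] + delta * dt1, y = y3[2L])
}
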