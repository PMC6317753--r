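#' Run configuration files
#'
#' Simulations can be described by a YAML or JSON configuration with the
#' blocks `params` (the six model constants, or `ratio_plus`/
#' `ratio_minus` plus `eta_v`, `f`, `k`, `k3`), `reality` (`type`:
#' `constant` | `step` | `random` with their parameters and, for
#' `random`, a mandatory `seed`), `init` (`m0`, `v0`), `horizon`,
#' optional `solver`, `interventions`, `qids`, and `output` paths.
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML/JSON).
#' @export
validate_run_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")))
  }
  check_keys(cfg, c("params", "reality", "init", "horizon", "solver",
                    "interventions", "qids", "output", "seed"), "config")
  for (req in c("params", "reality", "horizon"))
    if (is.null(cfg[[req]])) stop("config is missing required block: ", req)

  pb <- cfg$params
  check_keys(pb, c("eta_m_plus", "eta_m_minus", "eta_v", "f", "k", "k3",
                   "ratio_plus", "ratio_minus"), "params")
  params <- if (!is.null(pb$ratio_plus))
    mood_params_from_ratios(pb$ratio_plus, eta_v = pb$eta_v, f = pb$f,
                            k = pb$k, k3 = pb$k3,
                            ratio_minus = pb$ratio_minus %||% pb$ratio_plus)
  else
    mood_params(eta_m_plus = pb$eta_m_plus, eta_v = pb$eta_v, f = pb$f,
                k = pb$k, k3 = pb$k3,
                eta_m_minus = pb$eta_m_minus %||% pb$eta_m_plus)

  rb <- cfg$reality
  check_keys(rb, c("type", "r0", "breaks", "sigma_r", "k_r", "seed"),
             "reality")
  horizon <- as.numeric(cfg$horizon)
  reality <- switch(rb$type %||% stop("reality$type is required"),
    constant = constant_reality(rb$r0 %||% 0, horizon),
    step = step_reality(rb$breaks, horizon),
    random = {
      if (is.null(rb$seed))
        stop("a random reality requires an explicit reality$seed")
      random_reality(rb$sigma_r, rb$k_r, rb$seed, horizon)
    },
    stop("unknown reality$type: ", rb$type))

  ib <- cfg$init %||% list(m0 = 0, v0 = 0)
  check_keys(ib, c("m0", "v0"), "init")
  sb <- cfg$solver %||% list()
  check_keys(sb, c("rel_tol", "abs_tol", "max_step", "grid_dt",
                   "smooth_width"), "solver")
  opts <- do.call(solver_options, sb)
  qb <- cfg$qids %||% list()
  check_keys(qb, c("scale", "clip_max"), "qids")

  sched <- NULL
  if (!is.null(cfg$interventions) && length(cfg$interventions)) {
    evs <- lapply(cfg$interventions, function(ev) {
      check_keys(ev, c("time", "kind", "magnitude"), "interventions[]")
      intervention(ev$time, ev$kind, ev$magnitude)
    })
    sched <- do.call(intervention_schedule, evs)
  }
  ob <- cfg$output %||% list()
  check_keys(ob, c("trajectory", "report", "scan"), "output")

  structure(list(params = params, reality = reality,
                 init = c(ib$m0 %||% 0, ib$v0 %||% 0),
                 horizon = horizon, opts = opts, interventions = sched,
                 qids_scale = qb$scale %||% 1,
                 qids_clip_max = qb$clip_max %||% 27,
                 output = ob, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as CSV
#'
#' RFC-4180 CSV with a header row and columns
#' `time,m,v,r,branch,qids`.
#'
#' @param traj a `mood_trajectory`.
#' @param path output file path.
#' @param scale,clip_max QIDS conversion, see [qids_series()].
#' @export
write_trajectory <- function(traj, path, scale = 1, clip_max = 27) {
  df <- as.data.frame(traj)
  df$qids <- qids_series(traj, scale = scale, clip_max = clip_max)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("mood_trajectory", "data.frame")
  df
}

#' Execute a simulation run from a configuration
#'
#' Runs [simulate_mood()] as described by a configuration file or list,
#' writes the trajectory CSV and a JSON run report (config echo, package
#' version, final state, event log), and returns the trajectory.
#'
#' @param config a path to a config file or a validated `run_config`.
#' @param trajectory_csv,report_json optional output paths overriding the
#'   config's `output` block; `NULL` skips writing.
#' @return The `mood_trajectory`, invisibly, with the QIDS series
#'   attached as column `qids`.
#' @export
run_simulate <- function(config, trajectory_csv = NULL, report_json = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
    else if (inherits(config, "run_config")) config
    else validate_run_config(config)
  traj <- simulate_mood(cfg$params, cfg$reality, init = cfg$init,
                        horizon = cfg$horizon, opts = cfg$opts,
                        interventions = cfg$interventions)
  traj$qids <- qids_series(traj, scale = cfg$qids_scale,
                           clip_max = cfg$qids_clip_max)
  csv <- trajectory_csv %||% cfg$output$trajectory
  rep <- report_json %||% cfg$output$report
  if (!is.null(csv))
    write_trajectory(traj, csv, scale = cfg$qids_scale,
                     clip_max = cfg$qids_clip_max)
  if (!is.null(rep)) {
    n <- nrow(traj)
    report <- list(
      package = "moodcycle",
      version = as.character(utils::packageVersion("moodcycle")),
      config = cfg$raw,
      final_state = list(time = traj$time[n], m = traj$m[n], v = traj$v[n]),
      n_samples = n,
      event_log = attr(traj, "event_log"))
    jsonlite::write_json(report, rep, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(traj)
}

#' Linear stability from the command line or a script
#'
#' Thin wrapper over [predict_stability()] that optionally writes the
#' report as JSON.
#'
#' @param params a [mood_params()] object.
#' @param report_json optional output path.
#' @return The `stability_report`, invisibly.
#' @export
run_linstab <- function(params, report_json = NULL) {
  rep <- predict_stability(params)
  if (!is.null(report_json)) stability_report_json(rep, report_json)
  invisible(rep)
}

#' Run a stability or amplitude scan and write CSV output
#'
#' @param kind `"stability"` or `"amplitude"`.
#' @param csv optional output path for the long-format scan table.
#' @param header_json optional output path for the scan metadata
#'   (contour level, protocol).
#' @param args list of arguments for [stability_scan()] or
#'   [amplitude_scan()] (a list rather than `...` so that scan arguments
#'   such as `k` can never partially match this function's own).
#' @return The scan data frame, invisibly.
#' @export
run_scan <- function(kind = c("stability", "amplitude"), csv = NULL,
                     header_json = NULL, args = list()) {
  kind <- match.arg(kind)
  scan <- do.call(if (kind == "stability") stability_scan
                  else amplitude_scan, args)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(scan), csv, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(header_json)) {
    hdr <- list(kind = kind,
                contour_level = attr(scan, "contour_level"),
                protocol = attr(scan, "protocol"))
    jsonlite::write_json(hdr, header_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}
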