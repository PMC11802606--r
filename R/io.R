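# I/O: configuration loading (YAML/JSON), trajectory serialization with a
# metadata sidecar, and deterministic fixture trajectories for metric
# testing.

# Frozen CSV contract: column order and names are stable API.
.traj_csv_cols <- c("t_day", "t_since_infusion_day", "tumor_burden",
                    "car_t_level", "side_effects", "physical_wellbeing",
                    "psychological_wellbeing", "performance_status", "hrqol",
                    "coping_capacity", "infused", "alive")
.traj_int_cols <- c(t = "t_day", t_since_infusion = "t_since_infusion_day",
                    B = "tumor_burden", C = "car_t_level", S = "side_effects",
                    P = "physical_wellbeing", M = "psychological_wellbeing",
                    PS = "performance_status", Q = "hrqol",
                    kappa = "coping_capacity", infused = "infused",
                    alive = "alive")

#' Load a run configuration file
#'
#' YAML or JSON, auto-detected by extension. Recognized top-level keys:
#' `parameters` (named overrides of any model parameter), `scenario`,
#' `strategy`, `out_prefix`, `emit` (list with logical `trajectory`,
#' `metrics`, `plot`), `log_level`. Every model default is overridable; the
#' provenance of each parameter (default vs file) is retained for the run
#' log. Unknown keys and invariant violations raise a configuration error
#' naming the key.
#'
#' @param path config file path; an empty file yields pure defaults.
#' @return list with `params` (validated `qol_params`), `scenario`,
#'   `strategy`, `out_prefix`, `emit`, `log_level`, and a `provenance`
#'   character vector (`"default"` / `"file"`) over parameter names.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) .config_error("YAML parse failure in ", path,
                                               ": ", conditionMessage(e)))
  } else if (ext == "json") {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) .config_error("JSON parse failure in ", path,
                                               ": ", conditionMessage(e)))
  } else {
    .config_error("unrecognized config extension '", ext,
                  "' (expected .yaml, .yml or .json)")
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) .config_error("config root must be a mapping/object")

  known <- c("parameters", "scenario", "strategy", "out_prefix", "emit",
             "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .config_error("unknown config key(s): ", paste(unknown, collapse = ", "))

  defaults <- .param_defaults()
  ov <- raw$parameters %||% list()
  if (length(ov)) {
    if (!is.list(ov) || is.null(names(ov)) || any(!nzchar(names(ov))))
      .config_error("config key 'parameters' must be a named mapping")
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
      .config_error("unknown parameter key(s) in config: ",
                    paste(bad, collapse = ", "))
    defaults[names(ov)] <- ov
  }
  params <- validate_params(defaults)
  provenance <- stats::setNames(
    ifelse(names(defaults) %in% names(ov), "file", "default"),
    names(defaults))

  scenario <- raw$scenario %||% NULL
  if (!is.null(scenario)) scenario_spec(scenario)       # validate the name
  strategy <- raw$strategy %||% NULL
  if (!is.null(strategy)) strategy_spec(strategy)

  emit <- utils::modifyList(list(trajectory = TRUE, metrics = TRUE,
                                 plot = FALSE), raw$emit %||% list())
  list(params = params, scenario = scenario, strategy = strategy,
       out_prefix = raw$out_prefix %||% "cartqol_run",
       emit = emit, log_level = raw$log_level %||% "info",
       provenance = provenance)
}

#' Write a trajectory to CSV with a metadata sidecar
#'
#' One row per grid point, full float precision (round-trip exact). The
#' parameters, scenario/strategy labels, infusion record, death time and
#' package version go to `<path without ext>_meta.json`, from which the run
#' is fully reproducible.
#'
#' @param traj a `qol_trajectory`.
#' @param path output CSV path.
#' @return the CSV path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[names(.traj_int_cols)]
  names(df) <- unname(.traj_int_cols)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df$infused <- as.integer(df$infused)
  df$alive <- as.integer(df$alive)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)

  meta <- list(
    package = "cartqol",
    version = as.character(utils::packageVersion("cartqol")),
    parameters = unclass(attr(traj, "params")),
    scenario = attr(traj, "scenario"),
    strategy = attr(traj, "strategy"),
    infusion_time = attr(traj, "infusion_time"),
    death_time = attr(traj, "death_time"),
    infusion_record = attr(traj, "infusion_record"),
    max_excursion = attr(traj, "max_excursion"))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

.sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), "_meta.json")

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path the CSV path; the `_meta.json` sidecar is read when present.
#' @return a `qol_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = c(rep("numeric", 10L),
                                             "integer", "integer"))
  if (!identical(names(df), .traj_csv_cols))
    stop("malformed trajectory CSV: unexpected columns in ", path)
  names(df) <- names(.traj_int_cols)
  df$infused <- as.logical(df$infused)
  df$alive <- as.logical(df$alive)
  out <- structure(df, class = c("qol_trajectory", "data.frame"))
  side <- .sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "params") <- validate_params(meta$parameters)
    attr(out, "scenario") <- meta$scenario
    attr(out, "strategy") <- meta$strategy
    attr(out, "infusion_time") <- meta$infusion_time
    attr(out, "death_time") <- meta$death_time %||% NA_real_
    if (!is.null(meta$infusion_record))
      attr(out, "infusion_record") <- as.list(meta$infusion_record)
    attr(out, "max_excursion") <- meta$max_excursion
  }
  out
}

#' Deterministic fixture trajectories with closed-form metric values
#'
#' Builds a piecewise-linear HRQoL series on the model grid whose four
#' metrics are known by construction, for testing the metric computations
#' independently of the simulator. Well-being channels are set to the HRQoL
#' level itself (consistent with `Q = wQ*P + (1-wQ)*M`); the burden channel
#' is schematic (small after infusion, regrowing for the relapse wave).
#'
#' Shapes: `flat` (no dip, durable); `dip_recover` (dip of `drop`, recovery
#' at `recovery_days`, rise to `peak`, durable); `dip_no_recover` (dip, then
#' a plateau below the reference; never restored); `relapse_wave` (dip,
#' recovery, peak, terminal decline; not durable).
#'
#' @param shape one of `"flat"`, `"dip_recover"`, `"dip_no_recover"`,
#'   `"relapse_wave"`.
#' @param params a `qol_params` (grid and durability settings are honoured).
#' @param q0 pre-infusion HRQoL level.
#' @param drop constructed drop magnitude.
#' @param dip_days days from infusion to the minimum.
#' @param recovery_days days from infusion to restoration (must exceed
#'   `dip_days`).
#' @param peak constructed peak level (reached `2 * recovery_days` after
#'   infusion and held, except for the relapse wave's terminal decline).
#' @return a `qol_trajectory` with an attribute `truth`: the list of
#'   expected metric values the construction guarantees.
#' @export
make_fixture_trajectory <- function(shape = c("flat", "dip_recover",
                                              "dip_no_recover", "relapse_wave"),
                                    params = model_params(),
                                    q0 = 0.6, drop = 0.2, dip_days = NULL,
                                    recovery_days = NULL, peak = 0.75) {
  shape <- match.arg(shape)
  p <- validate_params(params)
  tvec <- seq(0, p$D + p$H, by = p$dt)
  Tend <- p$D + p$H
  snap <- function(x) max(p$dt, round(x / p$dt) * p$dt)  # grid-aligned
  if (is.null(dip_days)) dip_days <- snap(p$H / 18)
  if (is.null(recovery_days))
    recovery_days <- max(2 * dip_days, snap(p$H / 6))
  stopifnot(dip_days > 0, recovery_days > dip_days,
            p$D + 2 * recovery_days < Tend)
  interp <- function(knots_t, knots_q) stats::approx(knots_t, knots_q,
                                                     xout = tvec)$y
  tpk <- p$D + 2 * recovery_days
  truth <- switch(shape,
    flat = list(Qref = q0, drop = 0, recovery_days = 0, peak = q0,
                durable = TRUE),
    dip_recover = list(Qref = q0, drop = drop, recovery_days = recovery_days,
                       peak = peak, durable = TRUE),
    dip_no_recover = list(Qref = q0, drop = drop, recovery_days = NA_real_,
                          peak = q0 - drop / 2, durable = FALSE),
    relapse_wave = list(Qref = q0, drop = drop, recovery_days = recovery_days,
                        peak = peak, durable = FALSE))
  Q <- switch(shape,
    flat = rep(q0, length(tvec)),
    dip_recover = interp(
      c(0, p$D, p$D + dip_days, p$D + recovery_days, tpk, Tend),
      c(q0, q0, q0 - drop, q0, peak, peak)),
    dip_no_recover = interp(
      c(0, p$D, p$D + dip_days, p$D + recovery_days, Tend),
      c(q0, q0, q0 - drop, q0 - drop / 2, q0 - drop / 2)),
    relapse_wave = interp(
      c(0, p$D, p$D + dip_days, p$D + recovery_days, tpk, Tend),
      c(q0, q0, q0 - drop, q0, peak, peak - 0.15)))
  bknee <- p$D + min(20, p$H / 2)      # burden settles after the strike
  B <- switch(shape,
    flat = interp(c(0, p$D, bknee, Tend), c(0.2, 0.2, 0.005, 0.005)),
    dip_recover = interp(c(0, p$D, bknee, Tend), c(0.2, 0.2, 0.005, 0.005)),
    dip_no_recover = rep(0.2, length(tvec)),
    relapse_wave = interp(c(0, p$D, bknee, tpk, Tend),
                          c(0.2, 0.2, 0.1, 0.2, 0.5)))
  df <- data.frame(t = tvec, t_since_infusion = tvec - p$D,
                   B = B, C = ifelse(tvec < p$D, 0,
                                     0.3 * exp(-p$delta * (tvec - p$D))),
                   S = 0, P = Q, M = Q, PS = Q, Q = Q, kappa = 1,
                   infused = tvec >= p$D, alive = TRUE)
  structure(df, params = p, scenario = "fixture", strategy = shape,
            infusion_time = p$D, death_time = NA_real_,
            infusion_record = list(t = p$D, PS = q0, eta = 1, B = 0.2,
                                   Q = q0, eligible = TRUE),
            max_excursion = 0, truth = truth,
            class = c("qol_trajectory", "data.frame"))
}
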