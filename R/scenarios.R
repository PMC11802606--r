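# Scenarios and strategies: the three patient scenarios differ ONLY in the
# tumor growth rate g; the two improvement strategies touch only the
# approval-to-infusion delay D (60 -> 40 days) and the available daily social
# support Uavail (2 -> 6 h/day). No hidden per-scenario tuning.

.scenario_g <- c(complete_response = 0.006,
                 relapse           = 0.012,
                 no_infusion       = 0.020)

.strategy_overrides <- list(
  status_quo       = list(),
  reduced_delay    = list(D = 40),
  enhanced_support = list(Uavail = 6),
  combined         = list(D = 40, Uavail = 6)
)

#' List the built-in scenario / strategy names
#' @return character vector of preset names.
#' @export
list_scenarios <- function() names(.scenario_g)

#' @rdname list_scenarios
#' @export
list_strategies <- function() names(.strategy_overrides)

#' Scenario specification
#'
#' A scenario is a named tumor-growth-rate override: disease progression is
#' the only thing that distinguishes the complete-response, relapse and
#' no-infusion patients.
#'
#' @param name one of `"complete_response"`, `"relapse"`, `"no_infusion"`.
#' @return list with `name` and `g_override`.
#' @export
scenario_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% names(.scenario_g)))
    .config_error("unknown scenario '", paste(name, collapse = ","),
                  "'; valid scenarios: ", paste(names(.scenario_g), collapse = ", "))
  list(name = name, g_override = unname(.scenario_g[[name]]))
}

#' Strategy specification
#'
#' @param name one of `"status_quo"`, `"reduced_delay"`,
#'   `"enhanced_support"`, `"combined"`.
#' @return list with `name`, and any of `D_override`, `Uavail_override`.
#' @export
strategy_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.strategy_overrides)))
    .config_error("unknown strategy '", paste(name, collapse = ","),
                  "'; valid strategies: ",
                  paste(names(.strategy_overrides), collapse = ", "))
  ov <- .strategy_overrides[[name]]
  list(name = name,
       D_override = ov$D %||% NULL,
       Uavail_override = ov$Uavail %||% NULL)
}

#' Apply scenario and strategy overrides to a base parameter set
#'
#' Pure and idempotent: returns a new, re-validated parameter set in which
#' only `g` (scenario) and `D` and/or `Uavail` (strategy) are replaced. The
#' result carries `scenario` and `strategy` attributes for downstream
#' labelling.
#'
#' @param base a `qol_params` object.
#' @param scenario a scenario name or [scenario_spec()] result.
#' @param strategy a strategy name or [strategy_spec()] result.
#' @return a labelled `qol_params` object.
#' @export
#' @examples
#' p <- apply_overrides(model_params(), "relapse", "reduced_delay")
#' p$D       # 40
#' p$Uavail  # unchanged
apply_overrides <- function(base, scenario, strategy = "status_quo") {
  base <- validate_params(base)
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  p <- unclass(base)
  p$g <- scenario$g_override
  if (!is.null(strategy$D_override)) p$D <- strategy$D_override
  if (!is.null(strategy$Uavail_override)) p$Uavail <- strategy$Uavail_override
  p <- validate_params(p)
  attr(p, "scenario") <- scenario$name
  attr(p, "strategy") <- strategy$name
  p
}

#' Simulate a built-in scenario under a strategy
#'
#' Convenience wrapper: preset overrides + [simulate_trajectory()].
#'
#' @param scenario scenario name.
#' @param strategy strategy name.
#' @param base base parameters (defaults to [model_params()]).
#' @return a `qol_trajectory`.
#' @export
simulate_scenario <- function(scenario, strategy = "status_quo",
                              base = model_params()) {
  simulate_trajectory(apply_overrides(base, scenario, strategy))
}
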