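# Model parameters: every rate constant, weight, threshold, time constant and
# timing parameter of the coupled stock-flow system. All well-being-like
# quantities are normalized to [0, 1]; times are in days, support/obligation
# budgets in hours per day.

.param_defaults <- function() {
  list(
    ## timing
    D = 60,          # approval-to-infusion delay [day]
    H = 180,         # post-infusion horizon [day]
    dt = 0.125,      # integration step [day]; must divide D and H
    ## tumor
    g = 0.012,       # net tumor growth rate [/day]; the scenario knob
    alpha = 0.4,     # stage-acceleration coefficient [-]
    B0 = 0.31,       # initial tumor burden [0,1]
    ## CAR T-cell kinetics
    k = 1.0,        # kill-rate coefficient [/day per unit CAR-T]
    rho = 0.15,      # expansion rate [/day]
    delta = 0.20,    # contraction rate [/day]
    hB = 0.30,       # half-saturation burden for expansion [0,1]
    Cdose = 1.5,    # infused bolus [-]
    lambdaB = 1.4,  # burden-dependent efficacy penalty [-]
    Pref_eff = 0.55, # physical-well-being reference for efficacy gate (0,1]
    ## side effects
    sigma = 2.0,    # generation coefficient [-]
    mu = 1.0,        # physical-frailty amplification [-]
    m = 0.25,        # management (clearance) rate [/day]
    ## physical well-being
    rP = 0.08,       # adjustment rate [/day]
    wB = 1.50,       # weight of burden in the physical target [-]
    wS = 0.80,       # weight of side effects [-]
    wA = 0.25,       # weight of physical activity [-]
    omega = 0.60,    # own-state share in physical activity [0,1]
    ## psychological well-being
    rM = 0.03,      # adjustment rate [/day]
    mbase = 0.55,    # baseline psychological target [0,1]
    cact = 0.30,     # weight of psychosocial activity [-]
    cB = 0.05,       # weight of burden [-]
    cS = 0.10,       # weight of side effects [-]
    Pref_psy = 0.25, # physical gate for psychosocial activity (0,1]
    ## time budget / coping
    Tbasic = 10,     # non-discretionary hours (sleep, self-care) [h/day]
    Toblig = 8,      # baseline daily obligations [h/day]
    iota = 2.0,      # impairment multiplier on obligations [-]
    Uavail = 2,      # available daily social support [h/day]
    Tcope_ref = 6,   # hours needed for full-rate adaptation [h/day]
    ## HRQoL
    wQ = 0.6,        # weight of physical well-being in HRQoL [0,1]
    ## thresholds
    PSmin = 0.30,    # eligibility threshold on performance status [0,1]
    Pdeath = 0.03,   # death threshold on physical well-being [0,1]
    Bdeath = 0.995,  # death threshold on tumor burden [0,1]
    Bcr = 0.04,      # complete-response burden threshold [0,1]
    Brel = 0.25,     # relapse regrowth threshold [0,1]
    ## durability
    eps_peak = 0.90, # peak-retention fraction (0,1]
    eps_slope = 1e-3,# terminal slope tolerance [/day]
    Wdur = 30,       # durability assessment window [day]
    ## initial conditions
    P0 = 0.75,       # initial physical well-being [0,1]
    M0 = 0.45,       # initial psychological well-being [0,1]
    S0 = 0           # initial side-effect severity [0,1]
  )
}

.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("qol_config_error", "error", "condition")))
}

#' Construct a validated model parameter set
#'
#' Returns the calibrated default parameterization of the HRQoL stock-flow
#' model, with any number of named overrides. All overrides are validated
#' against the model invariants; a violation raises a configuration error
#' naming the offending parameter.
#'
#' @param ... named parameter overrides (see `.param_defaults` fields:
#'   timing `D`, `H`, `dt`; tumor `g`, `alpha`, `B0`; CAR-T `k`, `rho`,
#'   `delta`, `hB`, `Cdose`, `lambdaB`, `Pref_eff`; side effects `sigma`,
#'   `mu`, `m`; physical well-being `rP`, `wB`, `wS`, `wA`, `omega`;
#'   psychological well-being `rM`, `mbase`, `cact`, `cB`, `cS`, `Pref_psy`;
#'   time budget `Tbasic`, `Toblig`, `iota`, `Uavail`, `Tcope_ref`; HRQoL
#'   weight `wQ`; thresholds `PSmin`, `Pdeath`, `Bdeath`, `Bcr`, `Brel`;
#'   durability `eps_peak`, `eps_slope`, `Wdur`; initial state `P0`, `M0`,
#'   `S0`).
#' @return an object of class `qol_params` (a named list).
#' @export
#' @examples
#' p <- model_params()
#' p_fast <- model_params(D = 40)   # reduced-delay timing
model_params <- function(...) {
  p <- .param_defaults()
  ov <- list(...)
  if (length(ov)) {
    nm <- names(ov)
    if (is.null(nm) || any(!nzchar(nm)))
      .config_error("all parameter overrides must be named")
    unknown <- setdiff(nm, names(p))
    if (length(unknown))
      .config_error("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[nm] <- ov
  }
  validate_params(p)
}

.check_num <- function(p, name) {
  x <- p[[name]]
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .config_error("parameter '", name, "' must be a single finite number")
  x
}

#' Validate a model parameter set
#'
#' Enforces the structural invariants of the parameter space: non-negativity
#' of rates, weights and thresholds; unit-interval bounds for normalized
#' quantities; positive timing with `dt` dividing both `D` and `H`; the daily
#' time budget `Tbasic + Toblig <= 24`; and `Bcr < Brel`.
#'
#' @param p a named list of parameters (all fields required).
#' @return `p`, classed as `qol_params`, invisibly usable downstream.
#' @export
validate_params <- function(p) {
  need <- names(.param_defaults())
  missing <- setdiff(need, names(p))
  if (length(missing))
    .config_error("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), need)
  if (length(extra))
    .config_error("unknown parameter(s): ", paste(extra, collapse = ", "))
  for (nm in need) .check_num(p, nm)

  nonneg <- c("g", "alpha", "k", "rho", "delta", "Cdose", "lambdaB", "sigma",
              "mu", "m", "rP", "wB", "wS", "wA", "rM", "cact", "cB", "cS",
              "iota", "eps_slope")
  for (nm in nonneg)
    if (p[[nm]] < 0)
      .config_error("parameter '", nm, "' must be >= 0 (got ", p[[nm]], ")")

  unit <- c("B0", "P0", "M0", "S0", "hB", "omega", "wQ", "mbase",
            "PSmin", "Pdeath", "Bdeath", "Bcr", "Brel")
  for (nm in unit)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      .config_error("parameter '", nm, "' must lie in [0,1] (got ", p[[nm]], ")")

  pos_unit <- c("Pref_eff", "Pref_psy", "eps_peak")
  for (nm in pos_unit)
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      .config_error("parameter '", nm, "' must lie in (0,1] (got ", p[[nm]], ")")

  for (nm in c("D", "H", "dt", "Tcope_ref", "Wdur"))
    if (p[[nm]] <= 0)
      .config_error("parameter '", nm, "' must be > 0 (got ", p[[nm]], ")")

  for (nm in c("Tbasic", "Toblig"))
    if (p[[nm]] < 0)
      .config_error("parameter '", nm, "' must be >= 0 (got ", p[[nm]], ")")
  if (p$Tbasic + p$Toblig > 24)
    .config_error("parameters 'Tbasic' + 'Toblig' must not exceed 24 h/day (got ",
                  p$Tbasic + p$Toblig, ")")
  if (p$Uavail < 0 || p$Uavail > 24)
    .config_error("parameter 'Uavail' must lie in [0,24] h/day (got ", p$Uavail, ")")

  for (nm in c("D", "H")) {
    r <- p[[nm]] / p$dt
    if (abs(r - round(r)) > 1e-8)
      .config_error("parameter 'dt' (", p$dt, ") must divide '", nm, "' (", p[[nm]],
                    ") into an integer number of steps")
  }
  if (p$Bcr >= p$Brel)
    .config_error("parameter 'Bcr' (", p$Bcr, ") must be < 'Brel' (", p$Brel, ")")

  structure(p, class = "qol_params")
}

#' @export
print.qol_params <- function(x, ...) {
  cat("HRQoL model parameters (", length(x), " fields)\n", sep = "")
  cat(sprintf("  timing: D=%g d, H=%g d, dt=%g d\n", x$D, x$H, x$dt))
  cat(sprintf("  tumor: g=%g /d, alpha=%g, B0=%g\n", x$g, x$alpha, x$B0))
  cat(sprintf("  CAR-T: k=%g, rho=%g, delta=%g, Cdose=%g\n",
              x$k, x$rho, x$delta, x$Cdose))
  cat(sprintf("  support: Uavail=%g h/d, Toblig=%g h/d, Tbasic=%g h/d\n",
              x$Uavail, x$Toblig, x$Tbasic))
  invisible(x)
}
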