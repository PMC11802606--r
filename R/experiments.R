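# Experiment harness: the scenario x strategy matrix, the univariate +/-10%
# sensitivity analysis, and the extreme-condition test battery.

#' Run the scenario x strategy comparison matrix
#'
#' Simulates every (scenario, strategy) combination, computes the four
#' trajectory metrics and the response label, and appends per-scenario
#' deltas versus the status-quo strategy. Asserts nothing: qualitative
#' expectations live in the test suite.
#'
#' @param base base parameters (defaults to [model_params()]).
#' @param scenarios character vector of scenario names.
#' @param strategies character vector of strategy names.
#' @return a `qol_matrix` data.frame with one row per combination:
#'   `scenario`, `strategy`, `qref`, `drop`, `recovery_days`, `peak`,
#'   `durable`, `response`, `death_day`, `infused`, and (where a status-quo
#'   row exists for the scenario) `drop_delta`, `recovery_delta`,
#'   `peak_delta`, `durable_changed`.
#' @export
run_matrix <- function(base = model_params(),
                       scenarios = c("complete_response", "relapse", "no_infusion"),
                       strategies = c("status_quo", "reduced_delay", "enhanced_support")) {
  base <- validate_params(base)
  rows <- list()
  for (sc in sort(scenarios)) {
    for (st in sort(strategies)) {
      traj <- tryCatch(
        simulate_trajectory(apply_overrides(base, sc, st)),
        error = function(e) stop("matrix cell (", sc, ", ", st, "): ",
                                 conditionMessage(e), call. = FALSE))
      m <- compute_metrics(traj)
      rows[[paste(sc, st, sep = "|")]] <- data.frame(
        scenario = sc, strategy = st,
        qref = m$Qref, drop = m$drop, recovery_days = m$recovery_days,
        peak = m$peak, durable = m$durable, response = m$response,
        death_day = m$death_day,
        infused = any(traj$infused),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$drop_delta <- tab$recovery_delta <- tab$peak_delta <- NA_real_
  tab$durable_changed <- NA
  for (sc in unique(tab$scenario)) {
    ref <- tab[tab$scenario == sc & tab$strategy == "status_quo", ]
    if (nrow(ref) != 1L) next
    sel <- tab$scenario == sc
    tab$drop_delta[sel] <- tab$drop[sel] - ref$drop
    tab$recovery_delta[sel] <- tab$recovery_days[sel] - ref$recovery_days
    tab$peak_delta[sel] <- tab$peak[sel] - ref$peak
    tab$durable_changed[sel] <- tab$durable[sel] != ref$durable
  }
  class(tab) <- c("qol_matrix", "data.frame")
  tab
}

#' Default parameter set for the sensitivity analysis
#'
#' All continuous rate, weight, threshold and initial-condition parameters.
#' The structural timing parameters `dt`, `D` and `H` are excluded:
#' perturbing `D` or `H` moves the measurement time `Q(D+H)` itself, which
#' would confound the percent-change comparison.
#'
#' @return character vector of parameter names.
#' @export
default_sensitivity_params <- function() {
  c("g", "alpha", "B0", "k", "rho", "delta", "hB", "Cdose", "lambdaB",
    "Pref_eff", "sigma", "mu", "m", "rP", "wB", "wS", "wA", "omega",
    "rM", "mbase", "cact", "cB", "cS", "Pref_psy",
    "Tbasic", "Toblig", "iota", "Uavail", "Tcope_ref",
    "wQ", "P0", "M0", "S0", "PSmin", "Pdeath", "Bdeath", "Bcr", "Brel",
    "eps_peak", "eps_slope")
}

#' Univariate sensitivity analysis of final HRQoL
#'
#' For each listed parameter, runs the model with the parameter at
#' `(1 - rel)` and `(1 + rel)` times its base value (all else unchanged) and
#' records the percent change in HRQoL at the final simulation time versus
#' the unperturbed run. Perturbations that violate a parameter invariant
#' (e.g. a bounded fraction pushed above 1) keep their table row but are
#' flagged `skipped` with an `NA` value and a warning, so the +/-`rel`
#' semantics stay exact rather than silently clamped.
#'
#' @param base base parameters.
#' @param rel relative perturbation in `(0, 1)` (or 0 for the identity
#'   check).
#' @param scenario scenario anchoring the analysis; the default is the
#'   relapse scenario, which has the richest dynamics and survives to the
#'   horizon.
#' @param param_names parameters to perturb.
#' @return a `qol_sensitivity` data.frame: a baseline row (`direction`
#'   `"base"`, 0% change) plus two rows per parameter with `parameter`,
#'   `direction` (`"-"`/`"+"`), `value`, `q_final`, `pct_change`, `status`.
#' @export
run_sensitivity <- function(base = model_params(), rel = 0.10,
                            scenario = "relapse",
                            param_names = default_sensitivity_params()) {
  if (!is.numeric(rel) || length(rel) != 1L || rel < 0 || rel >= 1)
    .config_error("'rel' must be a fraction in [0, 1)")
  p0 <- apply_overrides(validate_params(base), scenario, "status_quo")
  traj0 <- simulate_trajectory(p0)
  qb <- traj0$Q[nrow(traj0)]
  if (qb <= 0)
    stop("sensitivity undefined: baseline final HRQoL is 0 (death at ",
         "horizon); choose a base scenario that survives to the horizon")
  unknown <- setdiff(param_names, names(.param_defaults()))
  if (length(unknown))
    .config_error("unknown parameter(s) in sensitivity list: ",
                  paste(unknown, collapse = ", "))

  rows <- list(data.frame(parameter = "(baseline)", direction = "base",
                          value = NA_real_, q_final = qb, pct_change = 0,
                          status = "ok", stringsAsFactors = FALSE))
  skipped <- character()
  for (nm in sort(param_names)) {
    for (dir in c("-", "+")) {
      fac <- if (dir == "-") 1 - rel else 1 + rel
      val <- p0[[nm]] * fac
      pp <- unclass(p0)
      pp[[nm]] <- val
      ok <- tryCatch({ validate_params(pp); TRUE },
                     qol_config_error = function(e) FALSE)
      if (!ok) {
        skipped <- c(skipped, paste0(nm, dir))
        rows[[paste0(nm, dir)]] <- data.frame(
          parameter = nm, direction = dir, value = val,
          q_final = NA_real_, pct_change = NA_real_, status = "skipped",
          stringsAsFactors = FALSE)
        next
      }
      tr <- simulate_trajectory(validate_params(pp),
                                scenario = scenario, strategy = "perturbed")
      qf <- tr$Q[nrow(tr)]
      rows[[paste0(nm, dir)]] <- data.frame(
        parameter = nm, direction = dir, value = val,
        q_final = qf, pct_change = 100 * (qf - qb) / qb, status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped perturbation(s) violating parameter invariants: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "rel") <- rel
  attr(tab, "scenario") <- scenario
  attr(tab, "q_base") <- qb
  class(tab) <- c("qol_sensitivity", "data.frame")
  tab
}

.extreme_check <- function(name, pass, witness, description) {
  data.frame(check = name, pass = pass, witness = witness,
             description = description, stringsAsFactors = FALSE)
}

#' Extreme-condition test battery
#'
#' Pushes the model to structural extremes and reports a named pass/fail
#' with observed witness values for each check: a tumor-free patient stays
#' tumor-free and alive; full initial burden nullifies dose efficacy; full
#' (24 h) support saturates coping capacity while zero support never exceeds
#' the baseline; without management, side effects are non-decreasing while
#' the kill flux is active; without tumor killing, infusion never pushes the
#' burden below its untreated path and yields no response; with zero
#' adjustment rates, well-being is frozen. Failures are report entries, not
#' exceptions.
#'
#' @param base base parameters (defaults to [model_params()]).
#' @return a `qol_extremes` data.frame with columns `check`, `pass`,
#'   `witness`, `description`.
#' @export
run_extreme_conditions <- function(base = model_params()) {
  base <- validate_params(base)
  sim <- function(...) simulate_trajectory(model_params_from(base, ...))
  out <- list()

  tr <- sim(g = 0, B0 = 0)
  out$tumor_free <- .extreme_check(
    "tumor_free", max(abs(tr$B)) <= 1e-12 && all(tr$alive),
    sprintf("max|B| = %.2e, deaths = %d", max(abs(tr$B)), sum(!tr$alive)),
    "g = 0, B0 = 0: burden identically zero and no death")

  tr <- sim(B0 = 1)
  rec <- attr(tr, "infusion_record")
  eta <- if (is.null(rec)) NA_real_ else rec$eta
  resp <- classify_response(tr)
  out$full_burden <- .extreme_check(
    "full_burden",
    (is.na(eta) || eta < 0.05) &&
      resp %in% c("not_infused", "died", "no_response"),
    sprintf("eta = %s, response = %s",
            if (is.na(eta)) "n/a (died pre-decision)" else format(eta), resp),
    "B0 = 1: dose efficacy ~0, no meaningful response")

  tr <- sim(Uavail = 24)
  out$full_support <- .extreme_check(
    "full_support", all(abs(tr$kappa - 1) <= 1e-12),
    sprintf("min kappa = %.6f", min(tr$kappa)),
    "Uavail = 24: coping capacity saturated at 1 throughout")

  tr0 <- simulate_trajectory(base)
  tr <- sim(Uavail = 0)
  out$no_support <- .extreme_check(
    "no_support", all(tr$kappa <= tr0$kappa + 1e-12),
    sprintf("max(kappa_0 - kappa_base) = %.2e", max(tr$kappa - tr0$kappa)),
    "Uavail = 0: coping capacity never exceeds the baseline run pointwise")

  tr <- sim(m = 0)
  flux <- tr$C * tr$B
  act <- which(flux[-nrow(tr)] > 1e-8 & flux[-1] > 1e-8)
  dS <- diff(tr$S)[act]
  out$no_management <- .extreme_check(
    "no_management", !length(dS) || min(dS) >= -1e-10,
    sprintf("min dS while C*B > 0: %.2e", if (length(dS)) min(dS) else 0),
    "m = 0: side effects non-decreasing while the kill flux is active")

  tr <- sim(k = 0)
  ref <- sim(k = 0, Cdose = 0)
  resp <- classify_response(tr)
  out$no_kill <- .extreme_check(
    "no_kill",
    all(tr$B >= ref$B - 1e-9) && resp %in% c("no_response", "died"),
    sprintf("min(B - B_untreated) = %.2e, response = %s",
            min(tr$B - ref$B), resp),
    "k = 0: infusion never reduces burden below the untreated path")

  tr <- sim(rP = 0, rM = 0)
  out$frozen_wellbeing <- .extreme_check(
    "frozen_wellbeing",
    max(abs(tr$P - base$P0)) <= 1e-12 && max(abs(tr$M - base$M0)) <= 1e-12,
    sprintf("max|P - P0| = %.2e, max|M - M0| = %.2e",
            max(abs(tr$P - base$P0)), max(abs(tr$M - base$M0))),
    "rP = rM = 0: physical and psychological well-being frozen")

  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("qol_extremes", "data.frame")
  tab
}

#' Rebuild a parameter set from a base with overrides
#'
#' Unlike [model_params()], which starts from the shipped defaults, this
#' keeps every value of `base` and replaces only the named fields, then
#' re-validates.
#'
#' @param base a `qol_params` object.
#' @param ... named overrides.
#' @return a validated `qol_params` object.
#' @export
model_params_from <- function(base, ...) {
  p <- unclass(validate_params(base))
  ov <- list(...)
  if (length(ov)) p[names(ov)] <- ov
  validate_params(p)
}

#' Write an experiment table to CSV
#'
#' One header row, snake_case columns, full float precision.
#'
#' @param tab a `qol_matrix`, `qol_sensitivity` or `qol_extremes` table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_table <- function(tab, path) {
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = which(!num), na = "")
  invisible(path)
}
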