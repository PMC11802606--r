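# Model core: state space, auxiliary signals, derivative field, and the two
# discrete events (infusion at t = D, death when a vital threshold is
# crossed). Time origin: t = 0 at treatment approval, infusion at t = D;
# reports additionally carry time-since-infusion so trajectories read on the
# clinical "time zero = infusion" axis.

.clamp01 <- function(x) min(max(x, 0), 1)

#' Initial model state
#'
#' @param params a `qol_params` object.
#' @return a named list with fields `t`, `B` (tumor burden), `C` (CAR-T
#'   level), `S` (side-effect severity), `P` (physical well-being), `M`
#'   (psychological well-being), `infused`, `alive`.
#' @export
initial_state <- function(params) {
  list(t = 0, B = params$B0, C = 0, S = params$S0,
       P = params$P0, M = params$M0, infused = FALSE, alive = TRUE)
}

# Pure auxiliary formulas on raw stock values. Single source of truth for
# both the user-facing compute_auxiliaries() and the integrator RHS.
.aux_core <- function(B, C, S, P, M, p) {
  PS <- P
  Q <- p$wQ * P + (1 - p$wQ) * M
  Aphys <- P * (p$omega + (1 - p$omega) * M)
  Apsy <- M * min(P / p$Pref_psy, 1)
  Teff <- max(p$Toblig * (1 + p$iota * (1 - PS)) - p$Uavail, 0)
  Ah <- max(24 - p$Tbasic - Teff, 0)
  kappa <- min(Ah / p$Tcope_ref, 1)
  Ptarget <- .clamp01(1 - p$wB * B - p$wS * S + p$wA * Aphys)
  Mtarget <- .clamp01(p$mbase + p$cact * Apsy - p$cB * B - p$cS * S)
  gate_eff <- min(P / p$Pref_eff, 1)
  eta <- .clamp01(1 - p$lambdaB * B) * gate_eff
  list(PS = PS, Q = Q, Aphys = Aphys, Apsy = Apsy,
       Teff = Teff, Ah = Ah, kappa = kappa,
       Ptarget = Ptarget, Mtarget = Mtarget,
       gate_eff = gate_eff, eta = eta)
}

# Derivative formulas; `aux` must come from .aux_core on the same stocks.
.deriv_core <- function(t, B, C, S, P, M, aux, p) {
  dB <- p$g * B * (1 - B) * (1 + p$alpha * B) - p$k * aux$gate_eff * C * B
  dC <- if (t < p$D) 0 else
    p$rho * C * (B / (B + p$hB)) * aux$gate_eff - p$delta * C
  dS <- p$sigma * p$k * C * B * (1 + p$mu * (1 - P)) * (1 - S) - p$m * S
  dP <- p$rP * (aux$Ptarget - P)
  dM <- p$rM * aux$kappa * (aux$Mtarget - M)
  c(dB = dB, dC = dC, dS = dS, dP = dP, dM = dM)
}

#' Compute the auxiliary signals of the model
#'
#' Auxiliaries are instantaneous functions of the stocks: performance status
#' `PS` (identified with physical well-being), HRQoL
#' `Q = wQ*P + (1-wQ)*M` (reported as 0 after death), physical and
#' psychosocial activity (`Aphys`, `Apsy`), the daily time budget and coping
#' capacity (`Teff`, `Ah`, `kappa`), the goal-seeking targets (`Ptarget`,
#' `Mtarget`), and the infusion efficacy multiplier `eta`.
#'
#' @param state a model state as returned by [initial_state()].
#' @param params a `qol_params` object.
#' @return a named list of auxiliary signals, all in `[0, 1]` except the
#'   hour-denominated intermediates `Teff` and `Ah`.
#' @export
compute_auxiliaries <- function(state, params) {
  params <- validate_params(params)
  aux <- .aux_core(state$B, state$C, state$S, state$P, state$M, params)
  if (!is.null(state$alive) && !state$alive) aux$Q <- 0
  aux
}

#' Compute the derivative field of the five stocks
#'
#' Net rates per day: logistic tumor growth with stage acceleration minus
#' CAR-T killing gated by physical well-being; burden-driven CAR-T expansion
#' (zero before infusion) minus contraction; side-effect generation on the
#' kill flux `C*B`, amplified by physical frailty and cleared at the
#' management rate; and first-order goal-seeking adjustment of physical and
#' psychological well-being, the latter rate-limited by coping capacity.
#'
#' @param state a model state; all stock components must be finite.
#' @param params a `qol_params` object.
#' @param aux auxiliaries from [compute_auxiliaries()] at `state`.
#' @return named list of rates `dB`, `dC`, `dS`, `dP`, `dM` (per day).
#' @export
compute_derivatives <- function(state, params, aux) {
  for (nm in c("B", "C", "S", "P", "M")) {
    if (!is.finite(state[[nm]]))
      stop("numerical error: non-finite state component '", nm, "'")
  }
  as.list(.deriv_core(state$t, state$B, state$C, state$S, state$P, state$M,
                      aux, params))
}

#' Apply the infusion event at the step boundary t = D
#'
#' At the reassessment the patient is eligible when performance status is at
#' least `PSmin`; if so the CAR-T stock receives the bolus `Cdose * eta`,
#' where `eta` discounts the dose for tumor burden and low physical
#' well-being. The returned eligibility record keeps `PS`, `eta`, tumor
#' burden and HRQoL at decision time (HRQoL just before the event is the
#' pre-infusion reference level used by the trajectory metrics).
#'
#' @param state a live model state at `t = D`.
#' @param params a `qol_params` object.
#' @return a list with elements `state` (post-event state) and `record`
#'   (decision-time `t`, `PS`, `eta`, `B`, `Q`, and logical `eligible`).
#' @export
apply_infusion <- function(state, params) {
  if (isTRUE(state$infused))
    stop("internal sequencing error: infusion already applied")
  if (abs(state$t - params$D) > 1e-9)
    stop("internal sequencing error: infusion must be applied at t = D (t = ",
         state$t, ", D = ", params$D, ")")
  if (!isTRUE(state$alive))
    stop("internal sequencing error: infusion applied to a non-live state")
  aux <- .aux_core(state$B, state$C, state$S, state$P, state$M, params)
  eligible <- aux$PS >= params$PSmin
  record <- list(t = state$t, PS = aux$PS, eta = aux$eta, B = state$B,
                 Q = aux$Q, eligible = eligible)
  if (eligible) {
    state$C <- state$C + params$Cdose * aux$eta
    state$infused <- TRUE
  }
  list(state = state, record = record)
}

#' Update vital status after an integration step
#'
#' Death occurs when physical well-being falls to `Pdeath` or below, or tumor
#' burden reaches `Bdeath` or above. Death is absorbing: a dead state is
#' returned unchanged (stocks frozen; the engine reports HRQoL as 0
#' thereafter).
#'
#' @param state a model state.
#' @param params a `qol_params` object.
#' @return the state with its `alive` flag updated.
#' @export
update_vital_status <- function(state, params) {
  if (!isTRUE(state$alive)) return(state)
  state$alive <- (state$P > params$Pdeath) && (state$B < params$Bdeath)
  state
}
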