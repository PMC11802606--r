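# Engine: fixed-step classical RK4 over [0, D+H], with the infusion event
# resolved exactly at the grid boundary t = D and death checked after every
# step. The model is fully deterministic: identical parameters yield
# bit-identical trajectories.

# RHS for the integrator: stocks as a length-5 vector (B, C, S, P, M).
.rhs <- function(t, y, p) {
  aux <- .aux_core(y[1L], y[2L], y[3L], y[4L], y[5L], p)
  .deriv_core(t, y[1L], y[2L], y[3L], y[4L], y[5L], aux, p)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances a live state by `dt` days, recomputing the auxiliaries at every
#' internal stage, then applies the safety clamp (stocks to `[0, 1]`, CAR-T
#' level to non-negative). The pre-clamp excursion beyond the bounds is
#' returned so callers can audit structural boundedness; the integrator never
#' relies on the clamp for stability.
#'
#' @param state a live model state.
#' @param params a `qol_params` object.
#' @param dt step size in days.
#' @return list with `state` (advanced state) and `excursion` (largest
#'   pre-clamp violation of the `[0, 1]` stock bounds, 0 if none).
#' @export
rk4_step <- function(state, params, dt) {
  p <- params
  y <- c(state$B, state$C, state$S, state$P, state$M)
  t <- state$t
  k1 <- .rhs(t, y, p)
  k2 <- .rhs(t + dt / 2, y + dt / 2 * k1, p)
  k3 <- .rhs(t + dt / 2, y + dt / 2 * k2, p)
  k4 <- .rhs(t + dt, y + dt * k3, p)
  for (s in 1:4) {
    ks <- switch(s, k1, k2, k3, k4)
    if (any(!is.finite(ks)))
      stop("numerical error: non-finite derivative at RK4 stage ", s,
           " (t = ", t, ")")
  }
  ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  bounded <- ynew[c(1L, 3L, 4L, 5L)]                 # B, S, P, M
  excursion <- max(0, -ynew[2L], -bounded, bounded - 1)
  state$B <- .clamp01(ynew[1L])
  state$C <- max(ynew[2L], 0)
  state$S <- .clamp01(ynew[3L])
  state$P <- .clamp01(ynew[4L])
  state$M <- .clamp01(ynew[5L])
  state$t <- t + dt
  list(state = state, excursion = excursion)
}

#' Simulate a full trajectory
#'
#' Integrates the model over `t` in `[0, D + H]` on the uniform grid `t = 0,
#' dt, ..., D + H`. The infusion decision is taken exactly at `t = D` (only
#' if the patient is still alive); vital status is updated after every step.
#' After death the remaining records continue with frozen stocks and HRQoL
#' reported as 0, so every trajectory has identical length.
#'
#' @param params a `qol_params` object.
#' @param scenario,strategy labels carried in the trajectory metadata
#'   (defaults taken from attributes set by [apply_overrides()], else
#'   `"custom"`).
#' @return a `qol_trajectory`: a data.frame with one row per grid point and
#'   columns `t`, `t_since_infusion`, `B`, `C`, `S`, `P`, `M`, `PS`, `Q`,
#'   `kappa`, `infused`, `alive`; attributes `params`, `scenario`,
#'   `strategy`, `infusion_time`, `death_time` (`NA` if alive at horizon),
#'   `infusion_record` (`NULL` if the decision was never reached) and
#'   `max_excursion` (largest pre-clamp bound violation seen).
#' @export
#' @examples
#' traj <- simulate_trajectory(model_params(dt = 0.5))
#' head(traj)
simulate_trajectory <- function(params,
                                scenario = NULL, strategy = NULL) {
  p <- validate_params(params)
  if (is.null(scenario))
    scenario <- attr(params, "scenario") %||% "custom"
  if (is.null(strategy))
    strategy <- attr(params, "strategy") %||% "custom"

  n <- as.integer(round((p$D + p$H) / p$dt))
  inf_step <- as.integer(round(p$D / p$dt))
  nr <- n + 1L
  tvec <- (0:n) * p$dt
  B <- C <- S <- P <- M <- PS <- Q <- kap <- numeric(nr)
  infused <- alive <- logical(nr)

  state <- initial_state(p)
  death_time <- NA_real_
  infusion_record <- NULL
  max_exc <- 0

  store <- function(i, state) {
    aux <- .aux_core(state$B, state$C, state$S, state$P, state$M, p)
    B[i] <<- state$B; C[i] <<- state$C; S[i] <<- state$S
    P[i] <<- state$P; M[i] <<- state$M
    PS[i] <<- aux$PS
    Q[i] <<- if (state$alive) aux$Q else 0
    kap[i] <<- aux$kappa
    infused[i] <<- state$infused
    alive[i] <<- state$alive
  }
  store(1L, state)

  for (i in seq_len(n)) {
    if (state$alive) {
      st <- rk4_step(state, p, p$dt)
      max_exc <- max(max_exc, st$excursion)
      state <- st$state
      state$t <- tvec[i + 1L]          # exact grid time (no drift)
      state <- update_vital_status(state, p)
      if (!state$alive && is.na(death_time)) death_time <- state$t
      if (state$alive && i == inf_step) {
        ev <- apply_infusion(state, p)
        state <- ev$state
        infusion_record <- ev$record
      }
    } else {
      state$t <- tvec[i + 1L]
    }
    store(i + 1L, state)
  }

  if (max_exc > 1e-6)
    warning("safety clamp engaged: pre-clamp excursion ", format(max_exc),
            " exceeds 1e-6; check step size / formulation")

  out <- data.frame(
    t = tvec, t_since_infusion = tvec - p$D,
    B = B, C = C, S = S, P = P, M = M,
    PS = PS, Q = Q, kappa = kap,
    infused = infused, alive = alive
  )
  structure(out,
            params = p, scenario = scenario, strategy = strategy,
            infusion_time = p$D, death_time = death_time,
            infusion_record = infusion_record, max_excursion = max_exc,
            class = c("qol_trajectory", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qol_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  if (is.null(p)) {            # subset without metadata: plain data.frame view
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("HRQoL trajectory: %s / %s, %d records over [0, %g] d (dt = %g)\n",
              attr(x, "scenario"), attr(x, "strategy"), nrow(x),
              p$D + p$H, p$dt))
  rec <- attr(x, "infusion_record")
  if (is.null(rec)) {
    cat("  infusion decision never reached\n")
  } else {
    cat(sprintf("  infusion decision at t = %g d: %s (PS = %.3f, eta = %.3f, B = %.3f)\n",
                rec$t, if (rec$eligible) "infused" else "declined",
                rec$PS, rec$eta, rec$B))
  }
  dth <- attr(x, "death_time")
  if (!is.na(dth)) cat(sprintf("  death at t = %g d\n", dth))
  cat(sprintf("  terminal HRQoL Q(%g) = %.4f\n", p$D + p$H, x$Q[nrow(x)]))
  invisible(x)
}

#' Plot HRQoL and stock trajectories
#'
#' Base-graphics view of a simulated trajectory: HRQoL with the infusion
#' time marked, plus the tumor burden, side-effect and well-being stocks.
#'
#' @param x a `qol_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.qol_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$Q, x$B, x$S, x$P, x$M),
                    type = "l", lty = c(1, 2, 3, 4, 5), lwd = c(2, 1, 1, 1, 1),
                    col = c("black", "firebrick", "darkorange", "steelblue", "seagreen"),
                    xlab = "time since approval [day]", ylab = "level [0-1]", ...)
  graphics::abline(v = attr(x, "infusion_time"), col = "grey40", lty = 3)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3, 4, 5),
                   col = c("black", "firebrick", "darkorange", "steelblue", "seagreen"),
                   legend = c("HRQoL", "tumor burden", "side effects",
                              "physical", "psychological"))
  invisible(x)
}
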