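# Trajectory metrics: the four HRQoL-dynamics measures (post-infusion drop,
# recovery time to the pre-infusion level, post-infusion peak, durability of
# the peak) plus the clinical response classification. All measures are
# computed on the sampled grid; no interpolation.

.traj_params <- function(traj, params = NULL) {
  p <- params %||% attr(traj, "params")
  if (is.null(p)) stop("trajectory carries no parameter metadata")
  validate_params(p)
}

#' Pre-infusion HRQoL reference level Q(D-)
#'
#' The reference against which the drop and the recovery are measured: HRQoL
#' at the infusion decision, evaluated just before the event. Trajectories
#' produced by [simulate_trajectory()] store this in their infusion record;
#' otherwise the value at the last grid point with `t < D + dt/2` is used.
#'
#' @param traj a `qol_trajectory`.
#' @return scalar HRQoL level in `[0, 1]`.
#' @export
pre_infusion_reference <- function(traj) {
  p <- .traj_params(traj)
  rec <- attr(traj, "infusion_record")
  if (!is.null(rec) && !is.null(rec$Q)) return(rec$Q)
  idx <- which(traj$t < p$D + p$dt / 2)
  if (!length(idx) || max(traj$t[idx]) < p$D - p$dt / 2)
    stop("malformed trajectory: no record at t = D = ", p$D)
  traj$Q[max(idx)]
}

#' Compute the four HRQoL-dynamics measures
#'
#' Over the post-infusion samples `t >= D`: the magnitude of the drop is
#' `Qref - min(Q)` (floored at 0, minimum taken at its first occurrence
#' `tmin`); the recovery time is the first `t >= tmin` with `Q >= Qref`,
#' counted in days since infusion (absent if never restored); the peak is the
#' maximum of `Q` on `t >= tmin` (after the dip, excluding the pre-dip
#' shoulder); durability is a dichotomous measure requiring survival to the
#' horizon, terminal retention `Q(D+H) >= eps_peak * peak`, a mean terminal
#' slope over the final `Wdur` days of at least `-eps_slope`, and (unless the
#' trajectory never dips below `Qref`) an observed recovery.
#'
#' @param traj a `qol_trajectory` (simulated or fixture).
#' @param params optional parameter override (defaults to trajectory
#'   metadata).
#' @return object of class `qol_metrics`: list with `Qref`, `drop`,
#'   `recovery_days` (`NA` if never restored), `peak`, `durable`, `response`,
#'   `death_day` (`NA` if alive at horizon).
#' @export
compute_metrics <- function(traj, params = NULL) {
  p <- .traj_params(traj, params)
  Qref <- pre_infusion_reference(traj)
  post <- traj$t >= p$D - 1e-9
  if (!any(post)) stop("malformed trajectory: no records at t >= D")
  tq <- traj$t[post]
  Q <- traj$Q[post]

  imin <- which.min(Q)                      # first occurrence of the minimum
  drop <- max(0, Qref - Q[imin])
  after <- imin:length(Q)
  irec <- after[which(Q[after] >= Qref - 1e-12)[1L]]
  recovery_days <- if (is.na(irec)) NA_real_ else tq[irec] - p$D
  peak <- max(Q[after])

  n <- length(Q)
  alive_end <- traj$alive[nrow(traj)]
  t_end <- tq[n]
  i0 <- which(tq >= t_end - p$Wdur - 1e-9)[1L]
  slope <- if (tq[n] > tq[i0]) (Q[n] - Q[i0]) / (tq[n] - tq[i0]) else 0
  no_dip <- drop <= 1e-12
  durable <- isTRUE(alive_end) &&
    Q[n] >= p$eps_peak * peak - 1e-12 &&
    slope >= -p$eps_slope &&
    (no_dip || !is.na(recovery_days))

  response <- classify_response(traj, p)
  if (response == "not_infused") durable <- FALSE

  structure(list(Qref = Qref, drop = drop, recovery_days = recovery_days,
                 peak = peak, durable = durable, response = response,
                 death_day = attr(traj, "death_time") %||% NA_real_),
            class = "qol_metrics")
}

#' Classify the clinical response of a trajectory
#'
#' `not_infused` if the infusion was declined (or never reached); `died` if
#' death occurred before the horizon; otherwise, on the post-infusion burden
#' series: `complete_response` if the burden minimum reaches `Bcr` and the
#' terminal burden stays at or below `Brel`; `relapse` if the minimum reaches
#' `Brel` and the burden subsequently rises above `Brel`; `no_response`
#' otherwise.
#'
#' @param traj a `qol_trajectory`.
#' @param params optional parameter override.
#' @return one of `"complete_response"`, `"relapse"`, `"no_response"`,
#'   `"not_infused"`, `"died"`.
#' @export
classify_response <- function(traj, params = NULL) {
  p <- .traj_params(traj, params)
  if (!any(traj$infused)) return("not_infused")
  dth <- attr(traj, "death_time")
  if (!is.null(dth) && !is.na(dth) && dth < p$D + p$H - 1e-9) return("died")
  if (!traj$alive[nrow(traj)]) return("died")
  post <- traj$t >= p$D - 1e-9
  B <- traj$B[post]
  imin <- which.min(B)
  minB <- B[imin]
  if (minB <= p$Bcr && B[length(B)] <= p$Brel) return("complete_response")
  if (minB <= p$Brel && any(B[imin:length(B)] > p$Brel)) return("relapse")
  "no_response"
}

#' @export
print.qol_metrics <- function(x, ...) {
  cat("HRQoL dynamics metrics\n")
  cat(sprintf("  pre-infusion reference Qref = %.4f\n", x$Qref))
  cat(sprintf("  drop                        = %.4f\n", x$drop))
  cat(sprintf("  recovery [days post-infusion] = %s\n",
              if (is.na(x$recovery_days)) "never restored"
              else format(x$recovery_days)))
  cat(sprintf("  peak                        = %.4f\n", x$peak))
  cat(sprintf("  durable                     = %s\n", x$durable))
  cat(sprintf("  response                    = %s\n", x$response))
  if (!is.na(x$death_day))
    cat(sprintf("  death at day                = %g\n", x$death_day))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Flat JSON object with snake_case keys; absent values (`NA`) are written as
#' `null`.
#'
#' @param metrics a `qol_metrics` object.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_metrics <- function(metrics, path = NULL) {
  x <- list(qref = metrics$Qref, drop = metrics$drop,
            recovery_days = metrics$recovery_days, peak = metrics$peak,
            durable = metrics$durable, response = metrics$response,
            death_day = metrics$death_day)
  x <- lapply(x, function(v) if (length(v) == 1L && is.na(v)) NULL else v)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
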