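# Independent brute-force oracle for the trajectory metrics: plain loops
# over the sampled series, written without reference to the package
# implementation.

oracle_metrics <- function(t, Q, D, eps_peak, eps_slope, Wdur, alive_end,
                           Qref) {
  post_i <- which(t >= D - 1e-9)
  tq <- t[post_i]
  q <- Q[post_i]
  n <- length(q)

  imin <- 1L
  for (i in seq_len(n)) if (q[i] < q[imin]) imin <- i
  drop <- Qref - q[imin]
  if (drop < 0) drop <- 0

  rec <- NA_real_
  for (i in imin:n) {
    if (q[i] >= Qref - 1e-12) { rec <- tq[i] - D; break }
  }

  peak <- q[imin]
  for (i in imin:n) if (q[i] > peak) peak <- q[i]

  i0 <- NA_integer_
  for (i in seq_len(n)) if (tq[i] >= tq[n] - Wdur - 1e-9) { i0 <- i; break }
  slope <- if (tq[n] > tq[i0]) (q[n] - q[i0]) / (tq[n] - tq[i0]) else 0

  durable <- isTRUE(alive_end) && q[n] >= eps_peak * peak - 1e-12 &&
    slope >= -eps_slope && (drop <= 1e-12 || !is.na(rec))

  list(drop = drop, tmin = tq[imin], recovery_days = rec, peak = peak,
       durable = durable)
}

# Random piecewise-linear fixture trajectory with an infusion record; used
# to compare compute_metrics() against the oracle on arbitrary shapes.
random_q_trajectory <- function(params) {
  p <- params
  tvec <- seq(0, p$D + p$H, by = p$dt)
  nk <- sample(4:9, 1)
  kt <- sort(c(0, p$D, p$D + p$H, runif(nk, 0, p$D + p$H)))
  kq <- runif(length(kt), 0.05, 0.95)
  Q <- stats::approx(kt, kq, xout = tvec)$y
  df <- data.frame(t = tvec, t_since_infusion = tvec - p$D, B = 0.1, C = 0,
                   S = 0, P = Q, M = Q, PS = Q, Q = Q, kappa = 1,
                   infused = tvec >= p$D, alive = TRUE)
  qd <- Q[which.min(abs(tvec - p$D))]
  structure(df, params = p, scenario = "fixture", strategy = "random",
            infusion_time = p$D, death_time = NA_real_,
            infusion_record = list(t = p$D, PS = qd, eta = 1, B = 0.1,
                                   Q = qd, eligible = TRUE),
            max_excursion = 0,
            class = c("qol_trajectory", "data.frame"))
}
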