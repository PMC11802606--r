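# Small helpers shared across tests.

# A fast grid for tests that exercise machinery rather than the calibrated
# dynamics: short delay and horizon, coarse step.
quick_params <- function(...) {
  model_params(D = 10, H = 20, dt = 0.25, ...)
}

# Random valid parameter sets for property sweeps. Ranges are generous but
# respect every declared invariant; timing is kept short so sweeps stay fast.
random_params <- function() {
  Tbasic <- runif(1, 6, 12)
  Toblig <- runif(1, 2, min(10, 24 - Tbasic))
  dt <- sample(c(0.25, 0.5), 1)
  D <- sample(c(5, 10, 20), 1)
  H <- sample(c(10, 20, 40), 1)
  model_params(
    D = D, H = H, dt = dt,
    g = runif(1, 0, 0.05), alpha = runif(1, 0, 2), B0 = runif(1, 0, 0.9),
    k = runif(1, 0, 0.8), rho = runif(1, 0, 1.5), delta = runif(1, 0, 0.5),
    hB = runif(1, 0.05, 0.5), Cdose = runif(1, 0, 1),
    lambdaB = runif(1, 0, 2), Pref_eff = runif(1, 0.3, 1),
    sigma = runif(1, 0, 4), mu = runif(1, 0, 2), m = runif(1, 0, 0.5),
    rP = runif(1, 0, 0.3), wB = runif(1, 0, 2), wS = runif(1, 0, 1.5),
    wA = runif(1, 0, 0.6), omega = runif(1, 0, 1),
    rM = runif(1, 0, 0.2), mbase = runif(1, 0.2, 0.9),
    cact = runif(1, 0, 0.6), cB = runif(1, 0, 0.5), cS = runif(1, 0, 0.5),
    Pref_psy = runif(1, 0.2, 1),
    Tbasic = Tbasic, Toblig = Toblig, iota = runif(1, 0, 3),
    Uavail = runif(1, 0, 12), Tcope_ref = runif(1, 2, 10),
    wQ = runif(1, 0, 1),
    PSmin = runif(1, 0.1, 0.6), Pdeath = runif(1, 0.01, 0.1),
    Bdeath = runif(1, 0.9, 1),
    P0 = runif(1, 0.3, 1), M0 = runif(1, 0.2, 1), S0 = runif(1, 0, 0.3))
}

# A random in-bounds state at a given time.
random_state <- function(t = 0, D = 10) {
  list(t = t, B = runif(1), C = runif(1, 0, 2), S = runif(1),
       P = runif(1), M = runif(1), infused = t >= D, alive = TRUE)
}
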