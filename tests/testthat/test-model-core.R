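# Unit tests for the auxiliary signals, derivative field and the two
# discrete events. Tests fix their own parameter values so they are
# independent of the shipped calibration.

aux_pars <- function(...) {
  model_params(wB = 0.7, wS = 0.6, wA = 0.3, omega = 0.6, wQ = 0.5,
               mbase = 0.45, cact = 0.5, cB = 0.4, cS = 0.3,
               Pref_psy = 0.5, Pref_eff = 0.7, lambdaB = 0.8,
               Tbasic = 10, Toblig = 8, iota = 1.5, Uavail = 2,
               Tcope_ref = 6, ...)
}

state_at <- function(B = 0, C = 0, S = 0, P = 1, M = 1, t = 0,
                     infused = FALSE, alive = TRUE) {
  list(t = t, B = B, C = C, S = S, P = P, M = M, infused = infused,
       alive = alive)
}

test_that("HRQoL is the stated convex combination and zero after death", {
  p <- aux_pars()
  expect_equal(compute_auxiliaries(state_at(P = 1, M = 1), p)$Q, 1)
  a <- compute_auxiliaries(state_at(P = 0.8, M = 0.4), p)
  expect_equal(a$Q, 0.5 * 0.8 + 0.5 * 0.4)
  dead <- compute_auxiliaries(state_at(P = 0.8, M = 0.4, alive = FALSE), p)
  expect_equal(dead$Q, 0)
})

test_that("activity terms vanish at zero physical well-being", {
  a <- compute_auxiliaries(state_at(P = 0, M = 0.7, B = 0.3, S = 0.2),
                           aux_pars())
  expect_equal(a$Aphys, 0)
  expect_equal(a$Apsy, 0)
})

test_that("time budget and coping capacity follow the stated arithmetic", {
  # healthy patient: obligations 8 h, support 2 h -> 6 h effective,
  # 8 adaptation hours, saturated coping
  a <- compute_auxiliaries(state_at(P = 1, M = 0.5), aux_pars())
  expect_equal(a$Teff, 6)
  expect_equal(a$Ah, 8)
  expect_equal(a$kappa, 1)
  # enhanced support (2 -> 6 h/day)
  a6 <- compute_auxiliaries(state_at(P = 1, M = 0.5), aux_pars(Uavail = 6))
  expect_equal(a6$Teff, 2)
  expect_equal(a6$Ah, 12)
  expect_equal(a6$kappa, 1)
  # impaired patient: obligations inflate, coping below saturation
  ai <- compute_auxiliaries(state_at(P = 0.5, M = 0.5), aux_pars())
  expect_equal(ai$Teff, 8 * (1 + 1.5 * 0.5) - 2)
  expect_equal(ai$kappa, (24 - 10 - ai$Teff) / 6)
})

test_that("targets and efficacy match hand-evaluated formulas", {
  p <- aux_pars()
  a <- compute_auxiliaries(state_at(B = 0.2, S = 0.1, P = 0.6, M = 0.5), p)
  aphys <- 0.6 * (0.6 + 0.4 * 0.5)
  expect_equal(a$Aphys, aphys)
  expect_equal(a$Apsy, 0.5 * 1)                     # P/Pref_psy saturates
  expect_equal(a$Ptarget, 1 - 0.7 * 0.2 - 0.6 * 0.1 + 0.3 * aphys)
  expect_equal(a$Mtarget, 0.45 + 0.5 * 0.5 - 0.4 * 0.2 - 0.3 * 0.1)
  expect_equal(a$eta, (1 - 0.8 * 0.2) * min(0.6 / 0.7, 1))
  # targets clamp to [0, 1]
  ah <- compute_auxiliaries(state_at(B = 1, S = 1, P = 0.2, M = 0.2), p)
  expect_equal(ah$Ptarget, 0)
  expect_gte(ah$Mtarget, 0)
})

test_that("derivative field has the structural zeros", {
  p <- aux_pars()
  s <- state_at(B = 0, C = 0.5, S = 0.2, P = 0.7, M = 0.6, t = 20)
  d <- compute_derivatives(s, p, compute_auxiliaries(s, p))
  expect_equal(d$dB, 0)                              # tumor-free fixed point
  expect_equal(d$dS, -p$m * 0.2)                     # no generation without B
  s1 <- state_at(B = 1, C = 0, P = 0.7, M = 0.6)
  d1 <- compute_derivatives(s1, p, compute_auxiliaries(s1, p))
  expect_equal(d1$dB, 0)                             # carrying capacity
  s2 <- state_at(B = 0.5, C = 0, P = 0.7, M = 0.6, t = 10)  # pre-infusion
  d2 <- compute_derivatives(s2, p, compute_auxiliaries(s2, p))
  expect_equal(d2$dC, 0)
  # goal-seeking equilibrium: zero adjustment at the target
  s3 <- state_at(B = 0.3, S = 0.1, P = 0.5, M = 0.5)
  a3 <- compute_auxiliaries(s3, p)
  a3$Ptarget <- s3$P
  a3$Mtarget <- s3$M
  d3 <- compute_derivatives(s3, p, a3)
  expect_equal(d3$dP, 0)
  expect_equal(d3$dM, 0)
})

test_that("non-finite states are rejected with the offending symbol", {
  p <- aux_pars()
  s <- state_at(B = 0.2, P = 0.6, M = 0.5)
  s$P <- NaN
  expect_error(compute_derivatives(s, p, list()), "'P'")
})

test_that("infusion eligibility, dosing, and sequencing guards", {
  p <- aux_pars(PSmin = 0.4, Cdose = 0.4, D = 60)
  # performance status below threshold: declined, CAR-T stays zero
  low <- state_at(P = 0.30, M = 0.5, B = 0.3, t = 60)
  r <- apply_infusion(low, p)
  expect_false(r$state$infused)
  expect_equal(r$state$C, 0)
  expect_false(r$record$eligible)
  # hand-evaluated dose: eta = (1 - 0.8*0.3) * min(0.9/0.7, 1) = 0.76
  ok <- state_at(P = 0.9, M = 0.5, B = 0.3, t = 60)
  r2 <- apply_infusion(ok, p)
  expect_true(r2$state$infused)
  expect_equal(r2$record$eta, 0.76)
  expect_equal(r2$state$C, 0.4 * 0.76)
  expect_equal(r2$record$Q, 0.5 * 0.9 + 0.5 * 0.5)
  # full burden nullifies the dose even when eligible
  full <- state_at(P = 0.9, M = 0.5, B = 1, t = 60)
  r3 <- apply_infusion(full, model_params(lambdaB = 1, PSmin = 0.4))
  expect_equal(r3$record$eta, 0)
  expect_equal(r3$state$C, 0)
  # sequencing errors
  expect_error(apply_infusion(r2$state, p), "sequencing")
  expect_error(apply_infusion(state_at(P = 0.9, t = 30), p), "sequencing")
})

test_that("vital status thresholds and the absorbing death state", {
  p <- model_params(Pdeath = 0.05, Bdeath = 0.99)
  s <- state_at(P = 0.04, M = 0.5, B = 0.3)
  expect_false(update_vital_status(s, p)$alive)
  s2 <- state_at(P = 0.5, M = 0.5, B = 0.5)
  expect_true(update_vital_status(s2, p)$alive)
  s3 <- state_at(P = 0.5, B = 0.995)
  expect_false(update_vital_status(s3, p)$alive)
  dead <- state_at(P = 0.9, B = 0.1)
  dead$alive <- FALSE
  expect_identical(update_vital_status(dead, p), dead)
})

test_that("coping capacity is monotone in support, obligations, impairment", {
  set.seed(101)
  for (i in 1:40) {
    p <- random_params()
    s <- random_state()
    k0 <- compute_auxiliaries(s, p)$kappa
    up <- function(nm, v) {
      q <- unclass(p); q[[nm]] <- v; validate_params(q)
    }
    if (p$Uavail + 1 <= 24)
      expect_gte(compute_auxiliaries(s, up("Uavail", p$Uavail + 1))$kappa, k0)
    if (p$Tbasic + p$Toblig + 1 <= 24)
      expect_lte(compute_auxiliaries(s, up("Toblig", p$Toblig + 1))$kappa, k0)
    expect_lte(compute_auxiliaries(s, up("iota", p$iota + 0.5))$kappa, k0)
  }
})

test_that("efficacy is monotone in burden and physical well-being", {
  set.seed(102)
  for (i in 1:40) {
    p <- random_params()
    s <- random_state()
    e0 <- compute_auxiliaries(s, p)$eta
    sB <- s; sB$B <- min(1, s$B + 0.1)
    expect_lte(compute_auxiliaries(sB, p)$eta, e0)
    sP <- s; sP$P <- min(1, s$P + 0.1)
    expect_gte(compute_auxiliaries(sP, p)$eta, e0)
  }
})

test_that("HRQoL lies between physical and psychological well-being", {
  set.seed(103)
  for (i in 1:40) {
    p <- random_params()
    s <- random_state()
    a <- compute_auxiliaries(s, p)
    expect_gte(a$Q, min(s$P, s$M) - 1e-12)
    expect_lte(a$Q, max(s$P, s$M) + 1e-12)
  }
})

test_that("one integration step preserves stock bounds structurally", {
  set.seed(104)
  worst <- 0
  for (i in 1:100) {
    p <- random_params()
    s <- random_state(t = runif(1, 0, p$D + p$H), D = p$D)
    st <- rk4_step(s, p, p$dt)
    worst <- max(worst, st$excursion)
  }
  expect_lt(worst, 1e-9)
})

test_that("with frozen tumor and side effects, well-being converges to the
           joint fixed point of the target maps", {
  # ample support keeps coping capacity saturated so the psychological
  # stock adjusts at full rate along the whole path
  p <- model_params(g = 0, k = 0, sigma = 0, B0 = 0.3, S0 = 0.2,
                    D = 10, H = 190, dt = 0.25, m = 0, Uavail = 14,
                    P0 = 0.4, M0 = 0.3, rP = 0.1, rM = 0.05)
  tr <- simulate_trajectory(p)
  expect_equal(max(abs(tr$B - 0.3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tr$S - 0.2)), 0, tolerance = 1e-12)
  # independent fixed-point solution by direct iteration of the target maps
  P <- p$P0; M <- p$M0
  for (i in 1:5000) {
    aphys <- P * (p$omega + (1 - p$omega) * M)
    apsy <- M * min(P / p$Pref_psy, 1)
    P <- min(max(1 - p$wB * 0.3 - p$wS * 0.2 + p$wA * aphys, 0), 1)
    M <- min(max(p$mbase + p$cact * apsy - p$cB * 0.3 - p$cS * 0.2, 0), 1)
  }
  n <- nrow(tr)
  expect_equal(tr$P[n], P, tolerance = 1e-3)
  expect_equal(tr$M[n], M, tolerance = 1e-3)
  # convergence is monotone component-wise
  expect_true(all(diff(tr$P) >= -1e-12) || all(diff(tr$P) <= 1e-12))
  expect_true(all(diff(tr$M) >= -1e-12) || all(diff(tr$M) <= 1e-12))
})
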