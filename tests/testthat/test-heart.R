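test_that("chamber pressure law reproduces its reference states", {
  lv <- chamber_params(2.5, 0.08, 20, Rs = 0, Esep = Inf, role = "LV")
  ## V = V_P0, q = 0, Ppc = 0, Esep -> Inf: P = 0 at any time
  for (t in c(0, 0.2, 0.5))
    expect_equal(chamber_pressure(20, t, lv, T = 0.8), 0)
  ## e(t) = 1 with no septal/resistive terms: pure ESPVR line
  act1 <- function(t) rep(1, length(t))
  V <- seq(40, 140, by = 20)
  P <- chamber_pressure(V, 0, lv, T = 0.8, activation = act1)
  expect_equal(P, 2.5 * (V - 20), tolerance = 1e-12)
  ## source resistance subtracts Rs q; septal term adds (Enat/Esep) P*
  lv2 <- chamber_params(2.5, 0.08, 20, Rs = 0.003, Esep = 60, role = "LV")
  expect_equal(chamber_pressure(100, 0, lv2, T = 0.8, q = 400, P_star = 24,
                                activation = act1),
               2.5 / 60 * 24 + 2.5 * 80 - 0.003 * 400, tolerance = 1e-12)
  expect_error(chamber_pressure(-5, 0, lv, T = 0.8), "V must be > 0")
  expect_error(chamber_params(Ees = 0.5, Emin = 0.8, V_P0 = 10), "Ees >= Emin")
})

test_that("activation waveforms are periodic, bounded and peak at one", {
  for (T in c(0.4, 0.8, 2.0)) {
    t <- seq(0, T, length.out = 4096)
    ev <- activation_double_hill(t, T)
    ea <- activation_atrial(t, T)
    expect_equal(max(ev), 1, tolerance = 1e-3)
    expect_true(all(ev >= 0 & ev <= 1 + 1e-12))
    expect_true(all(ea >= 0 & ea <= 1))
    expect_equal(activation_double_hill(0.1 + 3 * T, T),
                 activation_double_hill(0.1, T), tolerance = 1e-12)
  }
})

test_that("valve law: rectification, opening dynamics and steady Bernoulli", {
  v <- valve_params(Aann = 5e-4, leff = 0.01, Kvo = 0.3, Kvc = 0.3)
  ## sustained adverse gradient: flow decays to zero, valve closes
  st <- list(zeta = 1, q = 3e-4)
  for (k in 1:4000) st <- valve_flow(1e4, 1.3e4, v, st, dt = 1e-4)$state
  ## residual Bernoulli leak through the zmin floor area is sub-microlitre
  expect_lt(abs(st$q), 1e-6)
  expect_lt(st$zeta, 1e-3)
  ## constant forward gradient: steady flow matches the Bernoulli law
  st <- list(zeta = 0, q = 0)
  for (k in 1:20000) st <- valve_flow(1.4e4, 1e4, v, st, dt = 1e-4)$state
  expect_equal(st$zeta, 1, tolerance = 1e-6)
  expect_equal(st$q, valve_steady_flow(4e3, v), tolerance = 1e-3)
  ## ideal-diode debugging mode
  vd <- valve_params(mode = "diode")
  expect_equal(valve_flow(1e4, 2e4, vd, dt = 1e-3)$q, 0)
  expect_gt(valve_flow(2e4, 1e4, vd, dt = 1e-3)$q, 0)
})

test_that("contractility and heart-rate setters are pure and validated", {
  h <- heart_params()
  h2 <- set_contractility(h, 1.2)
  expect_equal(h2$chambers$LV$Ees, 1.2)
  expect_equal(set_contractility(h2, 2.5)$chambers$LV$Ees, 2.5)
  h2$chambers$LV$Ees <- h$chambers$LV$Ees
  expect_identical(h2, h)                      # nothing else was touched
  expect_warning(set_contractility(h, 5.5), "outside the studied range")
  expect_error(set_contractility(h, -1), "positive")
  h3 <- set_heart_rate(h, 100)
  expect_equal(h3$T, 0.6)
  expect_warning(set_heart_rate(h, 200), "outside the studied range")
})

test_that("the closed loop is physiological at control settings", {
  bl <- hw_baseline()
  sim <- bl$sim
  ht <- sim$heart_trace
  expect_true(sim$converged)
  ## calibration anchors of the packaged tree
  expect_equal(sim$co, 5.6, tolerance = 0.02)
  expect_equal(sim$lvedv, 136, tolerance = 0.05)
  ef <- 1 - min(ht$V_LV) / sim$lvedv
  expect_equal(ef, 0.55, tolerance = 0.05)
  ## PV-loop width (mL) times heart rate equals cardiac output within 1%
  sv_mL <- max(ht$V_LV) - min(ht$V_LV)
  expect_equal(sv_mL * 1e-3 * sim$hr, sim$co, tolerance = 0.01)
  ## stroke volume closes against the aortic valve outflow integral
  q_int_mL <- mean(ht$q_av) * sim$T      # mL/s trace over one period
  expect_equal(q_int_mL, sv_mL, tolerance = 0.005)
  ## aortic valve closure leaves a dicrotic notch in root pressure:
  ## a local minimum shortly after end-ejection, then a secondary rebound
  root <- sim$records$root
  i_pk <- which.max(ht$q_av)
  t_close <- ht$t[min(which(seq_along(ht$t) > i_pk & ht$q_av < 1))]
  win <- which(root$t > t_close & root$t < t_close + 0.1)
  Pw <- root$P[win]
  k <- 2:(length(Pw) - 1)
  loc_min <- k[Pw[k] < Pw[k - 1] & Pw[k] <= Pw[k + 1]]
  expect_gt(length(loc_min), 0)
  i_min <- loc_min[1]
  rebound <- max(Pw[i_min:min(i_min + 60, length(Pw))]) - Pw[i_min]
  expect_gt(rebound, 0.3 * MMHG_PA)
})

test_that("zero activation leaves a passive heart that stops pumping", {
  net <- make_reduced_tree()
  ch <- heart_params()$chambers
  for (nm in names(ch)) ch[[nm]]$Ees <- ch[[nm]]$Emin   # Enat constant
  h <- heart_params(chambers = ch)
  sim <- simulate_circulation(net, heart = h,
                              config = solver_config(tol = 1e-3,
                                                     cycles_max = 12))
  expect_lt(sim$co, 0.15)   # L/min; no contraction, no output
  root <- sim$records$root
  expect_lt(diff(range(root$P)) / MMHG_PA, 2)   # pulseless
})

test_that("end-systolic elastance is recovered from afterload variation", {
  ## clean elastance chambers: no pericardium, septal or resistive terms
  ch <- list(
    LA = chamber_params(0.45, 0.15, 4, Rs = 0, Esep = Inf, role = "LA"),
    LV = chamber_params(2.5, 0.08, 20, Rs = 0, Esep = Inf, role = "LV"),
    RA = chamber_params(0.30, 0.10, 4, Rs = 0, Esep = Inf, role = "RA"),
    RV = chamber_params(0.55, 0.05, 15, Rs = 0, Esep = Inf, role = "RV"))
  heart <- heart_params(chambers = ch,
                        pericardium = list(K = 0, V0 = 380, phi = 90))
  net <- make_reduced_tree()
  es <- vapply(c(0.6, 1.0, 1.6), function(f) {
    sim <- simulate_circulation(scale_bed_resistance(net, f), heart = heart,
                                config = solver_config(tol = 2e-4))
    ht <- sim$heart_trace
    i <- which.max(ht$P_LV / pmax(ht$V_LV - 20, 1))
    c(ht$V_LV[i], ht$P_LV[i])
  }, numeric(2))
  fit <- stats::lm(es[2, ] ~ es[1, ])
  expect_equal(unname(stats::coef(fit)[2]), 2.5, tolerance = 0.02)
  expect_equal(-unname(stats::coef(fit)[1] / stats::coef(fit)[2]), 20,
               tolerance = 0.05)
})

test_that("fixing cardiac output is a no-op at the fixed point and monotone", {
  bl <- hw_baseline()
  heart <- heart_params()
  ## target = the CO the default preload already delivers: zero iterations
  fx0 <- fix_cardiac_output(bl$net, heart, target_co = bl$sim$co,
                            config = solver_config(tol = 2e-4))
  expect_identical(fx0$iterations, 0L)
  expect_equal(fx0$pfill, heart$Pfill)
  ## lower contractility needs a larger preload for the same output
  fx_lo <- fix_cardiac_output(bl$net, set_contractility(heart, 1.2), 5.6,
                              config = solver_config(tol = 2e-4))
  fx_hi <- fix_cardiac_output(bl$net, set_contractility(heart, 5.0), 5.6,
                              config = solver_config(tol = 2e-4))
  expect_equal(fx_lo$co, 5.6, tolerance = 0.01)
  expect_equal(fx_hi$co, 5.6, tolerance = 0.01)
  expect_gt(fx_lo$lvedv, fx_hi$lvedv)
  expect_error(fix_cardiac_output(bl$net, heart, -2), "must be > 0")
  ## targets outside the studied CO range are flagged up front
  expect_warning(
    tryCatch(fix_cardiac_output(bl$net, heart, 0.2, max_iter = 1L),
             error = function(e) NULL),
    "outside the studied range")
})
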