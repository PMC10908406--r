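test_that("waveform records demand a uniform grid over one cycle", {
  t <- c(seq(0, 0.5, by = 0.001), 0.6)
  expect_error(waveform_record(t, P = seq_along(t)), "uniform")
  r <- hw_sine_record()
  expect_s3_class(r, "waveform_record")
  expect_equal(r$T, 0.8)
})

test_that("power decomposition matches the analytic sinusoid integrals", {
  ## constants: no pulsatile power at all
  n <- 1000L
  t <- (seq_len(n) - 1L) * 0.8 / n
  rc <- waveform_record(t, P = rep(1e4, n), Q = rep(2e-5, n))
  pw <- power_decomposition(rc)
  expect_equal(pw$P_pulse, 0)
  expect_equal(pw$P_total, 1e4 * 2e-5)
  ## in-phase sinusoids: P_pulse = a b / 2
  a <- 2e3; b <- 4e-6
  pw1 <- power_decomposition(hw_sine_record(a = a, b = b, phi = 0))
  expect_equal(pw1$P_pulse, a * b / 2, tolerance = 1e-10)
  ## phase shift: P_pulse = (a b / 2) cos(phi)
  for (phi in c(pi / 6, pi / 3, pi / 2, 2)) {
    pwp <- power_decomposition(hw_sine_record(a = a, b = b, phi = phi))
    expect_equal(pwp$P_pulse, a * b / 2 * cos(phi), tolerance = 1e-10)
  }
  ## identity P_total = P_s + P_pulse holds exactly by construction
  expect_identical(pw1$P_total, pw1$P_s + pw1$P_pulse)
  ## adding a constant to P changes the steady term only
  r2 <- hw_sine_record(); r2$P <- r2$P + 500
  expect_equal(power_decomposition(r2)$P_pulse,
               power_decomposition(hw_sine_record())$P_pulse,
               tolerance = 1e-10)
})

test_that("wave intensity signs follow the waterhammer identity", {
  rho <- 1050; c <- 6
  fw <- make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 2000, t0 = 0.2, width = 0.03)))
  wi <- wave_intensity(fw)
  expect_true(all(wi$dI >= -1e-8 * max(wi$dI)))
  ## dI = (dP/dt)^2 / (rho c) for a pure forward wave
  dt <- fw$t[2] - fw$t[1]
  n <- length(fw$P)
  dP <- (fw$P[c(2:n, 1)] - fw$P[c(n, 1:(n - 1))]) / (2 * dt)
  expect_equal(wi$dI, dP^2 / (rho * c), tolerance = 1e-8)
  bw <- make_waterhammer_waveforms(rho, c,
    backward = list(list(amp = 2000, t0 = 0.2, width = 0.03)))
  expect_true(all(wave_intensity(bw)$dI <= 1e-8 * max(abs(wave_intensity(bw)$dI))))
  ## flat signal: peaks undefined with a diagnostic
  n <- 1000L; t <- (seq_len(n) - 1L) * 0.8 / n
  flat <- waveform_record(t, P = rep(1e4, n), Q = rep(1e-5, n),
                          U = rep(0.1, n))
  wif <- wave_intensity(flat)
  expect_true(is.na(wif$FCWI))
  expect_match(attr(wif, "diagnostic"), "flat|forward")
})

test_that("the model's carotid wave pattern shows FCWI, BCWI, FEWI in order", {
  bl <- hw_baseline()
  wi <- wave_intensity(bl$sim$records$l_carotid)
  expect_gt(wi$FCWI, 0)
  expect_gt(wi$BCWI, 0)
  expect_gt(wi$FEWI, 0)
  expect_gt(wi$FCWI, wi$BCWI)        # dominant forward compression
  ## temporal order within the cycle, measured from the FCWI peak
  off <- function(t) (t - wi$t_FCWI) %% bl$sim$T
  expect_lt(off(wi$t_BCWI), off(wi$t_FEWI))
})

test_that("wave power is bilinear and peaks on the systolic upstroke", {
  r <- hw_baseline()$sim$records$l_carotid
  wp <- wave_power(r)
  expect_gt(wp$FCWP, 0)
  r2 <- r; r2$Q <- 2 * r2$Q
  expect_equal(wave_power(r2)$FCWP, 2 * wp$FCWP, tolerance = 1e-10)
  rq0 <- r; rq0$Q <- rep(0, length(r$Q))
  expect_equal(max(abs(wave_power(rq0)$WP)), 0)
  ## FCWP timing is consistent with the wave-intensity forward peak
  wi <- wave_intensity(r)
  expect_lt(abs(wp$t_FCWP - wi$t_FCWI), 0.1 * r$T)
})

test_that("wave separation recovers known compositions and is exact in sum", {
  rho <- 1050; c <- 6
  ## forward-only: backward residue under 1% of pulse pressure
  fw <- make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 3000, t0 = 0.25, width = 0.04)))
  sp <- wave_separation(fw, rho, c)
  expect_lt(max(abs(sp$P_backward - mean(sp$P_backward))),
            0.01 * diff(range(fw$P)))
  expect_equal(sp$P_forward + sp$P_backward, fw$P, tolerance = 1e-12)
  ## known two-component composition recovered within 2%
  rec <- make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 2500, t0 = 0.2, width = 0.03)),
    backward = list(list(amp = 1200, t0 = 0.45, width = 0.05)))
  sp2 <- wave_separation(rec, rho, c)
  Pf_true <- attr(rec, "P_forward"); Pb_true <- attr(rec, "P_backward")
  expect_lt(max(abs((sp2$P_forward - mean(sp2$P_forward)) -
                      (Pf_true - mean(Pf_true)))), 0.02 * 2500)
  expect_lt(max(abs((sp2$P_backward - mean(sp2$P_backward)) -
                      (Pb_true - mean(Pb_true)))), 0.02 * 2500)
  ## reversing the propagation direction (U -> -U) swaps forward and
  ## backward roles and negates the net wave-intensity integral
  rev <- rec
  rev$U <- -rec$U
  wi_f <- wave_intensity(rec); wi_r <- wave_intensity(rev)
  dt <- rec$t[2] - rec$t[1]
  expect_equal(sum(wi_r$dI) * dt, -sum(wi_f$dI) * dt, tolerance = 1e-9)
})

test_that("reflection index follows its conventions and error paths", {
  rho <- 1050; c <- 6
  ## constant backward component: RI = 0
  n <- 1000L; t <- (seq_len(n) - 1L) * 0.8 / n
  P <- 1e4 + 2000 * sin(2 * pi * t / 0.8)
  expect_equal(reflection_index(P, rep(3, n), P), 0)
  ## equal co-timed forward and backward amplitudes: the pressure pulse is
  ## their sum, so the backward share is 50%
  rec <- make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 2000, t0 = 0.3, width = 0.03)),
    backward = list(list(amp = 2000, t0 = 0.3, width = 0.03)))
  sp <- wave_separation(rec, rho, c)
  expect_equal(reflection_index(sp$P_forward, sp$P_backward, rec$P), 50,
               tolerance = 0.02)
  ## co-timed forward 2a + backward a: amplitude convention gives 33.3%
  rec2 <- make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 2000, t0 = 0.3, width = 0.04)),
    backward = list(list(amp = 1000, t0 = 0.3, width = 0.04)))
  sp2 <- wave_separation(rec2, rho, c)
  expect_equal(reflection_index(sp2$P_forward, sp2$P_backward, rec2$P),
               100 / 3, tolerance = 0.02)
  ## peak convention exists and differs in general
  ri_peak <- reflection_index(sp2$P_forward, sp2$P_backward, rec2$P,
                              convention = "peak")
  expect_true(is.finite(ri_peak))
  expect_error(reflection_index(P, rep(3, n), rep(1e4, n)), "zero pulse")
})

test_that("pulsatility index and cerebral blood flow behave as defined", {
  n <- 1000L; t <- (seq_len(n) - 1L) * 0.8 / n
  cst <- waveform_record(t, P = rep(1e4, n), Q = rep(2e-5, n))
  expect_equal(pulsatility_index(cst), 0)
  ## q = 1 + 0.5 sin: (1.5 - 0.5) / 1 = 1 exactly
  q <- 1 + 0.5 * sin(2 * pi * t / 0.8)
  r <- waveform_record(t, P = rep(1e4, n), Q = q)
  expect_equal(pulsatility_index(r), 1.0, tolerance = 1e-9)
  expect_error(pulsatility_index(waveform_record(t, P = q, Q = q - 2)),
               "nonpositive mean")
  ## CBF sums the four cycle means; self-reference gives 0% change
  mk <- function(qm) waveform_record(t, P = rep(1e4, n),
                                     Q = rep(qm * LMIN_M3S, n))
  recs <- list(mk(0.2), mk(0.2), mk(0.2), mk(0.2))
  cbf <- cerebral_blood_flow(recs)
  expect_equal(cbf$CBF, 0.8, tolerance = 1e-12)
  expect_equal(cerebral_blood_flow(recs, reference = cbf$CBF)$pct_change, 0)
  expect_error(cerebral_blood_flow(list(mk(0.2), NULL)), "missing")
})

test_that("analysis metrics are stable to the sampling rate above 500 Hz", {
  rho <- 1050; c <- 6
  mk <- function(n) make_waterhammer_waveforms(rho, c,
    forward = list(list(amp = 2500, t0 = 0.2, width = 0.05)),
    backward = list(list(amp = 1000, t0 = 0.45, width = 0.06)),
    T = 0.8, n = n)
  metrics <- function(r) {
    sp <- wave_separation(r, rho, c)
    c(cpp = power_decomposition(r)$P_pulse,
      cpi = pulsatility_index(r),
      ri = reflection_index(sp$P_forward, sp$P_backward, r$P))
  }
  m1 <- metrics(mk(400L))    # 500 Hz for T = 0.8
  m2 <- metrics(mk(1600L))   # 2 kHz
  expect_equal(m1, m2, tolerance = 5e-3)
})

test_that("hemodynamic_summary assembles every metric with units", {
  bl <- hw_baseline()
  hs <- hemodynamic_summary(bl$sim, bl$net)
  expect_true(all(c("CPP_mW", "CPI", "FCWI", "BCWI", "FEWI", "FCWP_W",
                    "RI_pct", "CBF_Lmin") %in% names(hs)))
  expect_equal(hs$P_total_mW, hs$P_s_mW + hs$CPP_mW, tolerance = 1e-9)
  expect_gt(hs$CBF_Lmin, 0.5); expect_lt(hs$CBF_Lmin, 1.2)
  expect_gt(hs$RI_pct, 10); expect_lt(hs$RI_pct, 60)
  expect_equal(hs$carotid_c0, 6.5, tolerance = 0.01)
  expect_error(hemodynamic_summary(bl$sim, bl$net, carotid = "nope"),
               "no record")
})
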