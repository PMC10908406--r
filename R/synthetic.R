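#' Reduced heart-aorta-brain arterial tree
#'
#' Generates the packaged synthetic fixture: a tapered aorta (ascending,
#' arch, thoracic, abdominal) with brachiocephalic, carotid, subclavian,
#' vertebral and brachial branches.  Both common carotids and both
#' vertebrals terminate in cerebral Windkessel beds; the arms and the
#' distal aorta terminate in limb/lower-body beds; the ascending aorta is
#' driven by the elastance heart.  This is an engineering stand-in for a
#' full arterial/venous parameterisation: quantitative full-model values
#' require a user-supplied transcription in the same network file format,
#' while qualitative wave behaviour is the fixture's purpose.
#'
#' Calibration is analytic: aortic wall coefficients are set so the
#' diastolic aortic wave speed equals `pwv_aortic`; bed resistances are set
#' so that the target flow split at the target mean pressure adds up to
#' `target_co`; each bed's proximal resistance is matched to the attached
#' vessel's characteristic impedance (with total bed resistance preserved).
#'
#' @param pwv_aortic baseline diastolic aortic pulse wave velocity (m/s).
#' @param pwv_carotid,pwv_vertebral,pwv_upper diastolic wave speeds of the
#'   muscular branches (m/s), not affected by aortic stiffness scaling.
#' @param target_co cardiac output the bed resistances are sized for (L/min).
#' @param map mean arterial pressure the beds are sized for (mmHg).
#' @param p_ven venous reference pressure (mmHg).
#' @param p_dias diastolic reference pressure (mmHg); the tube-law external
#'   pressure, at which each cross-section sits at its diastolic area.
#' @param flow_split named fractions of `target_co` per bed group:
#'   `carotid` (each), `vertebral` (each), `arm` (each), remainder to the
#'   lower body.
#' @param tau_systemic Windkessel drainage time constant `R2*C` for the
#'   limb and lower-body beds (s).
#' @param tau_cerebral drainage time constant of the four cerebral beds
#'   (s); the cerebrovascular time constant is much shorter than the
#'   systemic one (about 0.2-0.3 s in healthy adults), which makes the
#'   carotid flow track pressure rather than being buffered.
#' @param lower_r1_ratio ratio of the lower-body bed's proximal resistance
#'   to the characteristic impedance of the distal aorta.  Values above 1
#'   reproduce the effective aorto-iliac reflection site of the truncated
#'   lower body (the default gives a high-frequency reflection coefficient
#'   of about 1/3); the limb and cerebral beds stay impedance-matched.
#' @param rho,mu,xi blood properties, see [fluid_properties()].
#' @return a validated [network_spec()] whose site names match the defaults
#'   of [hemodynamic_summary()].
#' @export
make_reduced_tree <- function(pwv_aortic = 4.66,
                              pwv_carotid = 6.5, pwv_vertebral = 8.0,
                              pwv_upper = 7.0,
                              target_co = 5.6, map = 93, p_ven = 4.5,
                              p_dias = 80,
                              flow_split = c(carotid = 0.05,
                                             vertebral = 0.016,
                                             arm = 0.086),
                              tau_systemic = 1.3, tau_cerebral = 0.25,
                              lower_r1_ratio = 2.0,
                              rho = 1050, mu = 4e-3, xi = 9) {
  fluid <- fluid_properties(rho = rho, mu = mu, xi = xi)
  Pext <- p_dias * MMHG_PA

  seg <- function(id, name, L, dp, dd, c0, n) {
    Adp <- pi * (dp / 1000)^2 / 4
    Add <- pi * (dd / 1000)^2 / 4
    vessel_segment(id, name, L = L, d_prox = dp / 1000, d_dist = dd / 1000,
                   beta_prox = beta_for_wave_speed(c0, Adp, rho),
                   beta_dist = beta_for_wave_speed(c0, Add, rho),
                   Pext = Pext, n_nodes = n)
  }
  segs <- list(
    seg("asc_aorta",   "ascending aorta",   0.055, 30, 28, pwv_aortic, 7L),
    seg("arch_a",      "aortic arch I",     0.030, 28, 27, pwv_aortic, 4L),
    seg("arch_b",      "aortic arch II",    0.040, 27, 25, pwv_aortic, 5L),
    seg("thoracic_aorta", "thoracic aorta", 0.160, 25, 20, pwv_aortic, 17L),
    seg("abdominal_aorta", "abdominal aorta", 0.150, 20, 15, pwv_aortic, 16L),
    seg("brachioceph", "brachiocephalic",   0.035, 13, 12, pwv_upper, 4L),
    seg("r_carotid",   "right common carotid", 0.170, 8, 7, pwv_carotid, 18L),
    seg("l_carotid",   "left common carotid",  0.180, 8, 7, pwv_carotid, 19L),
    seg("r_subclavian", "right subclavian", 0.040, 9, 8.5, pwv_upper, 5L),
    seg("l_subclavian", "left subclavian",  0.040, 9, 8.5, pwv_upper, 5L),
    seg("r_vertebral", "right vertebral",   0.150, 4, 3.5, pwv_vertebral, 16L),
    seg("l_vertebral", "left vertebral",    0.150, 4, 3.5, pwv_vertebral, 16L),
    seg("r_brachial",  "right brachial",    0.080, 8, 7, pwv_upper, 9L),
    seg("l_brachial",  "left brachial",     0.080, 8, 7, pwv_upper, 9L))
  names(segs) <- vapply(segs, function(s) s$id, character(1))

  e <- function(s, end) list(segment = s, end = end)
  juncs <- list(
    junction(list(e("asc_aorta", "dist")),
             list(e("brachioceph", "prox"), e("arch_a", "prox"))),
    junction(list(e("arch_a", "dist")),
             list(e("l_carotid", "prox"), e("arch_b", "prox"))),
    junction(list(e("arch_b", "dist")),
             list(e("l_subclavian", "prox"), e("thoracic_aorta", "prox"))),
    junction(list(e("thoracic_aorta", "dist")),
             list(e("abdominal_aorta", "prox"))),
    junction(list(e("brachioceph", "dist")),
             list(e("r_carotid", "prox"), e("r_subclavian", "prox"))),
    junction(list(e("r_subclavian", "dist")),
             list(e("r_vertebral", "prox"), e("r_brachial", "prox"))),
    junction(list(e("l_subclavian", "dist")),
             list(e("l_vertebral", "prox"), e("l_brachial", "prox"))))

  ## bed sizing: total resistance from the target flow split at target MAP
  dP <- (map - p_ven) * MMHG_PA
  co_si <- target_co * LMIN_M3S
  frac <- c(r_carotid = flow_split[["carotid"]],
            l_carotid = flow_split[["carotid"]],
            r_vertebral = flow_split[["vertebral"]],
            l_vertebral = flow_split[["vertebral"]],
            r_brachial = flow_split[["arm"]],
            l_brachial = flow_split[["arm"]])
  frac <- c(frac, abdominal_aorta = 1 - sum(frac))
  if (frac[["abdominal_aorta"]] <= 0)
    stop("make_reduced_tree: flow_split exceeds the cardiac output")
  mk_bed <- function(seg_id) {
    Q <- frac[[seg_id]] * co_si
    Rtot <- dP / Q
    tau <- if (grepl("carotid|vertebral", seg_id)) tau_cerebral else tau_systemic
    bed <- windkessel_bed(R1 = 0.1 * Rtot, C = tau / (0.9 * Rtot),
                          R2 = 0.9 * Rtot, P_out = p_ven * MMHG_PA,
                          Pc = Pext * 0.98)
    bed <- match_characteristic_impedance(bed, segs[[seg_id]], end = "dist",
                                          fluid = fluid)
    if (seg_id == "abdominal_aorta") {
      Rt <- bed$R1 + bed$R2
      bed$R1 <- bed$R1 * lower_r1_ratio
      bed$R2 <- Rt - bed$R1
    }
    bed$C <- tau / bed$R2
    bed
  }
  terms <- c(list(terminal("asc_aorta", "prox", type = "heart")),
             lapply(names(frac), function(id)
               terminal(id, "dist", type = "windkessel", bed = mk_bed(id))))

  net <- network_spec(segs, juncs, terms,
                      aortic_ids = c("asc_aorta", "arch_a", "arch_b",
                                     "thoracic_aorta", "abdominal_aorta"),
                      fluid = fluid)
  attr(net, "calibration") <- list(
    pwv_aortic = pwv_aortic, target_co = target_co, map = map,
    flow_split = frac, tau_systemic = tau_systemic,
    tau_cerebral = tau_cerebral, lower_r1_ratio = lower_r1_ratio)
  net
}

#' Synthetic waterhammer waveforms of known composition
#'
#' Builds pressure and velocity waveforms from Gaussian pulses that are
#' exactly forward (\eqn{dP = +\rho c\,dU}) or backward
#' (\eqn{dP = -\rho c\,dU}) travelling, for use as ground-truth input to
#' wave intensity and wave separation.  The true components are attached as
#' attributes `P_forward` / `P_backward` (the forward component carries the
#' baseline pressure).
#'
#' @param rho blood density (kg/m^3).
#' @param c wave speed (m/s).
#' @param forward,backward lists of pulses, each
#'   `list(amp = <Pa>, t0 = <s>, width = <s>)`.
#' @param T period (s).
#' @param n samples.
#' @param P0 baseline pressure (Pa).
#' @param U0 baseline velocity (m/s).
#' @param A cross-sectional area (m^2) used for the flow channel.
#' @return a [waveform_record()] with attributes `P_forward`, `P_backward`.
#' @export
make_waterhammer_waveforms <- function(rho = 1050, c = 6,
                                       forward = list(), backward = list(),
                                       T = 0.8, n = 1000L,
                                       P0 = 80 * MMHG_PA, U0 = 0,
                                       A = 3e-5) {
  t <- (seq_len(n) - 1L) * T / n
  gauss <- function(p) p$amp * exp(-(t - p$t0)^2 / (2 * p$width^2))
  Pf <- Reduce(`+`, lapply(forward, gauss), numeric(n))
  Pb <- Reduce(`+`, lapply(backward, gauss), numeric(n))
  P <- P0 + Pf + Pb
  U <- U0 + (Pf - Pb) / (rho * c)
  rec <- waveform_record(t = t, P = P, Q = A * U, U = U,
                         A = rep(A, n), site = "synthetic")
  attr(rec, "P_forward") <- P0 + Pf
  attr(rec, "P_backward") <- Pb
  rec
}

#' Single-vessel Windkessel verification case
#'
#' One uniform vessel with a prescribed periodic half-sine inflow at the
#' proximal end and a Windkessel bed at the distal end, bundled with its
#' analytic oracles: the DC outlet pressure
#' \eqn{P_{out} + (R_1 + R_2)\bar Q}, the pulse transit time \eqn{L/c_0}
#' and the inlet reflection-return time \eqn{2L/c_0}.
#'
#' @param L vessel length (m).
#' @param d diameter (mm).
#' @param c0 diastolic wave speed (m/s).
#' @param n_nodes spatial resolution.
#' @param R_total total bed resistance (Pa s/m^3); proximal share set by
#'   characteristic-impedance matching.
#' @param tau_bed bed time constant R2*C (s).
#' @param P_out bed outflow pressure (Pa).
#' @param P_dias diastolic reference pressure (Pa).
#' @param Q_peak peak inflow (m^3/s).
#' @param t_sys inflow pulse duration (s).
#' @param T period (s).
#' @param match_bed match R1 to the characteristic impedance (default);
#'   otherwise R1 = 0.1 R_total.
#' @param rho,mu,xi blood properties.
#' @return list with `net` ([network_spec()]), `inflow` (function of time),
#'   `T`, `Q_mean`, and `oracle` (list of the analytic expectations).
#' @export
make_single_vessel_case <- function(L = 0.25, d = 10, c0 = 5, n_nodes = 26L,
                                    R_total = 1.4e8, tau_bed = 1.3,
                                    P_out = 4.5 * MMHG_PA,
                                    P_dias = 80 * MMHG_PA,
                                    Q_peak = 4e-4, t_sys = 0.3, T = 0.8,
                                    match_bed = TRUE,
                                    rho = 1050, mu = 4e-3, xi = 9) {
  fluid <- fluid_properties(rho = rho, mu = mu, xi = xi)
  Ad <- pi * (d / 1000)^2 / 4
  vs <- vessel_segment("vessel", "test vessel", L = L,
                       d_prox = d / 1000, d_dist = d / 1000,
                       beta_prox = beta_for_wave_speed(c0, Ad, rho),
                       Pext = P_dias, n_nodes = n_nodes)
  bed <- windkessel_bed(R1 = 0.1 * R_total, C = tau_bed / (0.9 * R_total),
                        R2 = 0.9 * R_total, P_out = P_out, Pc = P_dias)
  if (match_bed) {
    bed <- match_characteristic_impedance(bed, vs, end = "dist", fluid = fluid)
    bed$C <- tau_bed / bed$R2
  }
  net <- network_spec(list(vs), junctions = list(),
                      terminals = list(
                        terminal("vessel", "prox", type = "heart"),
                        terminal("vessel", "dist", type = "windkessel",
                                 bed = bed)),
                      aortic_ids = "vessel", fluid = fluid)
  inflow <- function(t) {
    tt <- t %% T
    ifelse(tt < t_sys, Q_peak * sin(pi * tt / t_sys), 0)
  }
  Q_mean <- Q_peak * 2 * t_sys / (pi * T)
  list(net = net, inflow = inflow, T = T, Q_mean = Q_mean,
       oracle = list(P_mean_out = P_out + (bed$R1 + bed$R2) * Q_mean,
                     transit_time = L / c0,
                     reflection_return = 2 * L / c0,
                     c0 = c0))
}
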