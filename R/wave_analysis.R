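#' Sampled waveforms at a site over one converged cycle
#'
#' Container for uniformly sampled pressure, flow, velocity and area over
#' one cardiac period.  The grid covers \eqn{[0, T)} without a duplicated
#' endpoint, so cycle averages are plain means and periodic differences wrap
#' around.
#'
#' @param t uniform time grid (s), first sample 0.
#' @param P pressure (Pa).
#' @param Q volumetric flow (m^3/s).
#' @param U mean axial velocity (m/s).
#' @param A cross-sectional area (m^2).
#' @param site site label.
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(t, P, Q = NULL, U = NULL, A = NULL, site = "") {
  n <- length(t)
  if (n < 8L) stop("waveform_record: need at least 8 samples")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("waveform_record: time grid must be uniform")
  for (nm in c("P", "Q", "U", "A")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop(sprintf("waveform_record: %s has wrong length", nm))
  }
  structure(list(t = t, P = P, Q = Q, U = U, A = A, site = site,
                 T = n * dt[1]), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> '%s': %d samples over T = %.4g s\n",
              x$site, length(x$t), x$T))
  cat(sprintf("  P %.1f-%.1f mmHg, Qmean %.3g L/min\n",
              min(x$P) / MMHG_PA, max(x$P) / MMHG_PA,
              if (!is.null(x$Q)) mean(x$Q) / LMIN_M3S else NA))
  invisible(x)
}

## centred periodic finite difference, d/dt
.ddt_periodic <- function(v, dt) {
  n <- length(v)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * dt)
}

.check_cycle <- function(rec) {
  if (!inherits(rec, "waveform_record"))
    stop("expected a waveform_record (one full cycle)")
  dt <- diff(rec$t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("non-uniform time grid")
  invisible(dt[1])
}

#' Decompose transmitted power into steady and pulsatile parts
#'
#' Cycle-averaged hydraulic power
#' \eqn{\bar P_{total} = \frac{1}{T}\int_0^T P(t)Q(t)\,dt}, its steady part
#' \eqn{\bar P_s = P_{mean} Q_{mean}} and the pulsatile remainder
#' \eqn{\bar P_{pulse} = \bar P_{total} - \bar P_s} (identically, by
#' construction).  On the periodic uniform grid the trapezoidal cycle
#' integral reduces to the sample mean.
#'
#' @param rec a [waveform_record()] with `P` and `Q`.
#' @return list with `P_total`, `P_s`, `P_pulse` (W), `Pmean` (Pa),
#'   `Qmean` (m^3/s).
#' @export
power_decomposition <- function(rec) {
  .check_cycle(rec)
  if (is.null(rec$Q)) stop("power_decomposition: record lacks Q")
  P_total <- mean(rec$P * rec$Q)
  Pm <- mean(rec$P); Qm <- mean(rec$Q)
  P_s <- Pm * Qm
  list(P_total = P_total, P_s = P_s, P_pulse = P_total - P_s,
       Pmean = Pm, Qmean = Qm)
}

#' Wave intensity and its systolic peaks
#'
#' Time-normalised wave intensity
#' \eqn{dI(t) = (dP/dt)(dU/dt)} (W m^-2 s^-2) from centred differences,
#' together with the three fiducial peaks of the carotid/aortic pattern:
#' the forward compression peak FCWI (early-systolic, `dP/dt > 0` and
#' `dU/dt > 0`), the backward compression trough BCWI (reported as a
#' positive magnitude) between FCWI and the forward expansion peak FEWI
#' (late-systolic, `dP/dt < 0` and `dU/dt < 0`).
#'
#' @param rec a [waveform_record()] with `P` and `U`.
#' @param smooth optional Savitzky-Golay half-window (samples) applied to
#'   `P` and `U` before differencing (needs the `signal` package); 0 = none
#'   (solver output is smooth).
#' @return list with the series `dI`, peak values `FCWI`, `BCWI`, `FEWI`
#'   (all >= 0; `NA` with a `diagnostic` attribute if a landmark cannot be
#'   identified), their times, and `t`.
#' @export
wave_intensity <- function(rec, smooth = 0) {
  dt <- .check_cycle(rec)
  if (is.null(rec$U)) stop("wave_intensity: record lacks U")
  P <- rec$P; U <- rec$U
  if (smooth > 0) {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("wave_intensity: smoothing needs the 'signal' package")
    P <- signal::sgolayfilt(P, p = 3, n = 2 * smooth + 1)
    U <- signal::sgolayfilt(U, p = 3, n = 2 * smooth + 1)
  }
  dP <- .ddt_periodic(P, dt)
  dU <- .ddt_periodic(U, dt)
  dI <- dP * dU
  n <- length(dI)
  res <- list(t = rec$t, dI = dI, FCWI = NA_real_, BCWI = NA_real_,
              FEWI = NA_real_, t_FCWI = NA_real_, t_BCWI = NA_real_,
              t_FEWI = NA_real_)
  fwd <- dP > 0 & dU > 0
  if (!any(fwd) || max(dI[fwd]) <= 0) {
    attr(res, "diagnostic") <- "no forward compression region (flat signals?)"
    return(res)
  }
  i1 <- which(fwd)[which.max(dI[fwd])]
  res$FCWI <- dI[i1]; res$t_FCWI <- rec$t[i1]
  ## work in cyclic offset from the FCWI peak
  off <- ((seq_len(n) - i1) %% n)   # samples after the peak
  bwd_exp <- dP < 0 & dU < 0 & off > 0.02 * n & off < 0.7 * n
  if (any(bwd_exp)) {
    cand <- which(bwd_exp)
    ie <- cand[which.max(dI[cand])]
    res$FEWI <- max(dI[ie], 0); res$t_FEWI <- rec$t[ie]
    mid <- off > 0 & off < off[ie]
    if (any(mid) && min(dI[mid]) < 0) {
      im <- which(mid)[which.min(dI[mid])]
      res$BCWI <- -dI[im]; res$t_BCWI <- rec$t[im]
    } else attr(res, "diagnostic") <- "no backward compression trough"
  } else attr(res, "diagnostic") <- "no forward expansion region"
  res
}

#' Wave power and its forward compression peak
#'
#' Wave power is built from the pulsatile pressure-flow product
#' \eqn{WP(t) = (P - P_{mean})(Q - Q_{mean})} (W); unlike wave intensity it
#' uses volumetric flow and is therefore insensitive to cross-sectional
#' area.  FCWP is the amplitude of the first systolic peak, located on the
#' joint pressure/flow upstroke consistent with the FCWI timing.
#'
#' @param rec a [waveform_record()] with `P` and `Q`.
#' @return list with the series `WP`, `FCWP` (W) and `t_FCWP`.
#' @export
wave_power <- function(rec) {
  dt <- .check_cycle(rec)
  if (is.null(rec$Q)) stop("wave_power: record lacks Q")
  WP <- (rec$P - mean(rec$P)) * (rec$Q - mean(rec$Q))
  dP <- .ddt_periodic(rec$P, dt)
  dQ <- .ddt_periodic(rec$Q, dt)
  up <- dP > 0 & dQ > 0
  res <- list(t = rec$t, WP = WP, FCWP = NA_real_, t_FCWP = NA_real_)
  if (!any(up)) {
    attr(res, "diagnostic") <- "no joint upstroke region"
    return(res)
  }
  i <- which(up)[which.max(WP[up])]
  res$FCWP <- WP[i]; res$t_FCWP <- rec$t[i]
  res
}

#' Separate a pressure waveform into forward and backward components
#'
#' Linear (waterhammer) wave separation about cycle means:
#' \eqn{dP_f = (dP + \rho c\,dU)/2}, \eqn{dP_b = (dP - \rho c\,dU)/2},
#' cumulatively summed and re-anchored so that
#' \eqn{P_f + P_b = P} exactly, with the mean pressure assigned to the
#' forward component.
#'
#' @param rec a [waveform_record()] with `P` and `U`.
#' @param rho blood density (kg/m^3).
#' @param c wave speed at the site (m/s); conventionally the diastolic
#'   value \eqn{c_0}.
#' @return list with `t`, `P_forward`, `P_backward` (Pa).
#' @export
wave_separation <- function(rec, rho, c) {
  dt <- .check_cycle(rec)
  if (c <= 0) stop("wave_separation: c must be > 0")
  if (is.null(rec$U)) stop("wave_separation: record lacks U")
  dP <- .ddt_periodic(rec$P, dt) * dt
  dU <- .ddt_periodic(rec$U, dt) * dt
  dPf <- (dP + rho * c * dU) / 2
  dPb <- (dP - rho * c * dU) / 2
  Pf <- cumsum(dPf); Pb <- cumsum(dPb)
  ## de-drift (periodic signals have zero net increment up to roundoff)
  n <- length(Pf)
  drift <- function(v) v - (seq_len(n) - 1L) / n * v[n]
  Pf <- drift(Pf); Pb <- drift(Pb)
  ## anchor: components sum to the raw waveform, mean carried by Pf
  Pb <- Pb - mean(Pb)
  Pf <- rec$P - Pb
  list(t = rec$t, P_forward = Pf, P_backward = Pb)
}

#' Reflection index from separated pressure components
#'
#' Ratio of the backward pressure amplitude to the total pressure
#' amplitude, in percent.  Two conventions for "amplitude" are provided:
#' `"pulse"` (default) uses peak-to-trough excursions of \eqn{P_b} and
#' \eqn{P}; `"peak"` uses the maximum deviations from the respective cycle
#' means.
#'
#' @param P_forward,P_backward separated components (Pa), as returned by
#'   [wave_separation()].
#' @param P total pressure (Pa).
#' @param convention `"pulse"` or `"peak"`.
#' @return reflection index (%).
#' @export
reflection_index <- function(P_forward, P_backward, P,
                             convention = c("pulse", "peak")) {
  convention <- match.arg(convention)
  pp <- diff(range(P))
  if (pp <= 0) stop("reflection_index: zero pulse pressure")
  if (convention == "pulse")
    100 * diff(range(P_backward)) / pp
  else
    100 * max(abs(P_backward - mean(P_backward))) / max(abs(P - mean(P)))
}

#' Flow pulsatility index
#'
#' \eqn{(q_{max} - q_{min}) / \bar q} of the flow waveform over one cycle;
#' for the carotid this is the carotid pulsatility index (CPI).
#'
#' @param rec a [waveform_record()] with `Q`, or a numeric flow vector.
#' @return dimensionless pulsatility index.
#' @export
pulsatility_index <- function(rec) {
  q <- if (inherits(rec, "waveform_record")) rec$Q else as.numeric(rec)
  if (is.null(q)) stop("pulsatility_index: record lacks Q")
  qm <- mean(q)
  if (qm <= 0) stop("pulsatility_index: nonpositive mean flow, index undefined")
  (max(q) - min(q)) / qm
}

#' Cerebral blood flow from the brain-supplying arteries
#'
#' Sums the cycle-mean flow of the records for the arteries feeding the
#' brain (both common carotids and both vertebrals in the full topology).
#'
#' @param records list of [waveform_record()]s, one per brain-supplying
#'   artery from the same converged simulation.
#' @param reference optional reference CBF (L/min) against which a percent
#'   change is computed (e.g. the baseline-stiffness run of the same heart
#'   settings).
#' @return list with `CBF` (L/min) and `pct_change` (% vs `reference`, `NA`
#'   if no reference given).
#' @export
cerebral_blood_flow <- function(records, reference = NULL) {
  if (!length(records)) stop("cerebral_blood_flow: no records given")
  ok <- vapply(records, function(r)
    inherits(r, "waveform_record") && !is.null(r$Q), logical(1))
  if (!all(ok))
    stop("cerebral_blood_flow: missing or flow-less record at position ",
         which(!ok)[1])
  cbf <- sum(vapply(records, function(r) mean(r$Q), numeric(1))) / LMIN_M3S
  pct <- if (is.null(reference)) NA_real_ else 100 * (cbf - reference) / reference
  list(CBF = cbf, pct_change = pct)
}

#' Full hemodynamic summary of a converged simulation
#'
#' Computes every analysis metric at the carotid monitoring site (power
#' decomposition, wave intensity peaks, wave power, wave separation and
#' reflection index, pulsatility index) plus cerebral blood flow over the
#' named brain-supplying sites.
#'
#' @param sim a `circ_sim` from [simulate_circulation()].
#' @param net the [network_spec()] that produced `sim` (used for the site
#'   wave speed entering the separation).
#' @param carotid name of the carotid analysis site (a record in `sim`, by
#'   default the site named after the left common carotid segment).
#' @param carotid_pos fractional position of that site along its segment.
#' @param cerebral names of the brain-supplying records summed into CBF.
#' @param ri_convention passed to [reflection_index()].
#' @return one-row `data.frame`: powers in mW, WI peaks in W m^-2 s^-2,
#'   FCWP in W, RI in %, CBF in L/min, flows in mL/s, pressures in mmHg.
#' @export
hemodynamic_summary <- function(sim, net, carotid = "l_carotid",
                                carotid_pos = 0.5,
                                cerebral = c("l_carotid", "r_carotid",
                                             "l_vertebral", "r_vertebral"),
                                ri_convention = "pulse") {
  rec <- sim$records[[carotid]]
  if (is.null(rec))
    stop(sprintf("hemodynamic_summary: no record named '%s'", carotid))
  seg <- net$segments[[carotid]]
  if (is.null(seg))
    stop(sprintf("hemodynamic_summary: no segment '%s' for wave speed", carotid))
  x <- carotid_pos * seg$L
  c0 <- wave_speed(segment_Ad(seg, x), x, seg, net$fluid)
  pw <- power_decomposition(rec)
  wi <- wave_intensity(rec)
  wp <- wave_power(rec)
  sep <- wave_separation(rec, net$fluid$rho, c0)
  ri <- reflection_index(sep$P_forward, sep$P_backward, rec$P,
                         convention = ri_convention)
  cpi <- pulsatility_index(rec)
  cbf <- cerebral_blood_flow(sim$records[intersect(cerebral,
                                                   names(sim$records))])
  data.frame(
    P_total_mW = 1000 * pw$P_total,
    P_s_mW = 1000 * pw$P_s,
    CPP_mW = 1000 * pw$P_pulse,
    CPI = cpi,
    FCWI = wi$FCWI, BCWI = wi$BCWI, FEWI = wi$FEWI,
    FCWP_W = wp$FCWP,
    RI_pct = ri,
    CBF_Lmin = cbf$CBF,
    qmin_mLs = min(rec$Q) / ML_M3, qmax_mLs = max(rec$Q) / ML_M3,
    Pmean_mmHg = pw$Pmean / MMHG_PA,
    Qmean_mLs = pw$Qmean / ML_M3,
    carotid_c0 = c0)
}
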