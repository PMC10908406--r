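#' Parameters of one heart chamber
#'
#' A chamber of the time-varying elastance heart.  The pressure-volume
#' relation is
#' \deqn{P = P_{pc} + \frac{E_{nat}}{E_{sep}} P^{*} + E_{nat}(t)\,(V - V_{P=0}) - R_s q,}
#' with native elastance \eqn{E_{nat}(t) = E_{min} + e(t)(E_{es} - E_{min})},
#' normalized activation \eqn{e(t) \in [0, 1]}, pericardial pressure
#' \eqn{P_{pc}}, septal elastance \eqn{E_{sep}} coupling to the contralateral
#' chamber pressure \eqn{P^{*}}, and source resistance \eqn{R_s} acting on the
#' chamber outflow \eqn{q}.
#'
#' Elastances are in clinical units (mmHg/mL), volumes in mL, resistances in
#' mmHg s/mL; conversion to SI happens inside the solver.
#'
#' @param Ees end-systolic elastance (mmHg/mL).
#' @param Emin diastolic (passive) elastance (mmHg/mL).
#' @param V_P0 zero-pressure volume (mL).
#' @param Rs source resistance (mmHg s/mL).
#' @param Esep septal elastance (mmHg/mL); `Inf` decouples the chambers.
#' @param role one of `"LA"`, `"LV"`, `"RA"`, `"RV"`.
#' @return an object of class `chamber_params`.
#' @export
chamber_params <- function(Ees, Emin, V_P0, Rs = 0, Esep = Inf,
                           role = c("LV", "LA", "RA", "RV")) {
  role <- match.arg(role)
  if (!(Ees >= Emin) || Emin <= 0)
    stop("chamber_params: need Ees >= Emin > 0")
  if (V_P0 < 0) stop("chamber_params: V_P0 must be >= 0")
  if (Rs < 0) stop("chamber_params: Rs must be >= 0")
  structure(list(Ees = Ees, Emin = Emin, V_P0 = V_P0, Rs = Rs,
                 Esep = Esep, role = role), class = "chamber_params")
}

#' Normalized double-Hill activation waveform
#'
#' The standard smooth contraction-relaxation shape used by elastance heart
#' models,
#' \deqn{e(t) \propto \frac{(t/\tau_1)^{m_1}}{1 + (t/\tau_1)^{m_1}} \cdot
#'       \frac{1}{1 + (t/\tau_2)^{m_2}},}
#' rescaled so its maximum over the period is exactly 1.
#'
#' @param t time within the cycle (s), vector.
#' @param T cycle length (s).
#' @param tau1,tau2 contraction and relaxation time scales (s).
#' @param m1,m2 Hill exponents.
#' @param onset activation onset time within the cycle (s); the waveform is
#'   evaluated in cyclic time `t - onset`.
#' @return numeric vector in \eqn{[0, 1]} with max 1.
#' @export
activation_double_hill <- function(t, T, tau1 = 0.269 * 0.8 * sqrt(T / 0.8),
                                   tau2 = 0.452 * 0.8 * sqrt(T / 0.8),
                                   m1 = 1.32, m2 = 27.4, onset = 0) {
  g <- function(tt) {
    tt <- tt %% T
    a <- (tt / tau1)^m1
    (a / (1 + a)) / (1 + (tt / tau2)^m2)
  }
  tt <- seq(0, T, length.out = 4096L)
  peak <- max(g(tt))
  pmin(g(t - onset) / peak, 1)
}

#' Atrial activation bump
#'
#' A raised-sine contraction of duration `dur` starting at `onset` (cyclic
#' time), used for the atria which contract in late diastole just before
#' ventricular systole.
#'
#' @inheritParams activation_double_hill
#' @param dur contraction duration (s).
#' @return numeric vector in \eqn{[0, 1]}.
#' @export
activation_atrial <- function(t, T, dur = 0.2 * sqrt(T * 0.8), onset = T - 0.9 * dur) {
  tt <- (t - onset) %% T
  ifelse(tt < dur, sin(pi * tt / dur)^2, 0)
}

#' Instantaneous chamber pressure (time-varying elastance law)
#'
#' Direct evaluation of the chamber pressure-volume relation (see
#' [chamber_params()]).  All quantities in clinical units: volumes mL, flows
#' mL/s, pressures mmHg.
#'
#' @param V chamber volume (mL), > 0.
#' @param t time within the cycle (s).
#' @param params a [chamber_params()].
#' @param T cycle length (s).
#' @param q chamber outflow (mL/s), penalised by the source resistance.
#' @param P_star contralateral chamber pressure (mmHg).
#' @param Ppc pericardial pressure (mmHg).
#' @param activation optional function `e(t)` overriding the default
#'   (double-Hill for ventricles, atrial bump for atria).
#' @return pressure (mmHg).
#' @export
chamber_pressure <- function(V, t, params, T = 0.8, q = 0, P_star = 0,
                             Ppc = 0, activation = NULL) {
  if (any(V <= 0)) stop("chamber_pressure: V must be > 0")
  if (is.null(activation)) {
    activation <- if (params$role %in% c("LV", "RV"))
      function(t) activation_double_hill(t, T)
    else function(t) activation_atrial(t, T)
  }
  e <- activation(t)
  Enat <- params$Emin + e * (params$Ees - params$Emin)
  sep <- if (is.finite(params$Esep)) (Enat / params$Esep) * P_star else 0
  Ppc + sep + Enat * (V - params$V_P0) - params$Rs * q
}

#' Valve parameters
#'
#' Pressure-gradient-driven valve with first-order opening/closing dynamics
#' of the opening state \eqn{\zeta \in [0,1]} and a Bernoulli resistance plus
#' blood inertance through the effective open area
#' \eqn{A_{eff} = \zeta A_{ann}}:
#' \deqn{\frac{d\zeta}{dt} = \begin{cases}(1-\zeta)K_{vo}\Delta P & \Delta P > 0\\
#'       \zeta K_{vc}\Delta P & \Delta P \le 0\end{cases}, \qquad
#'       L\frac{dq}{dt} = \Delta P - B\,q|q|,}
#' with \eqn{B = \rho/(2A_{eff}^2)} and \eqn{L = \rho\,l_{eff}/A_{eff}}.
#'
#' @param Aann annulus area (m^2).
#' @param leff effective inertial length (m).
#' @param Kvo,Kvc opening/closing rate constants (1/(Pa s)).
#' @param zmin floor on the opening state used for the effective area (keeps
#'   the closed-valve leak negligible but the ODE well-posed).
#' @param mode `"dynamic"` (default) or `"diode"` (instantaneous ideal valve,
#'   for debugging).
#' @return an object of class `valve_params`.
#' @export
valve_params <- function(Aann = 5e-4, leff = 0.01, Kvo = 0.3, Kvc = 0.3,
                         zmin = 1e-5, mode = c("dynamic", "diode")) {
  mode <- match.arg(mode)
  if (Aann <= 0 || leff <= 0) stop("valve_params: Aann and leff must be > 0")
  structure(list(Aann = Aann, leff = leff, Kvo = Kvo, Kvc = Kvc,
                 zmin = zmin, mode = mode), class = "valve_params")
}

#' Advance a valve one time step
#'
#' R-level reference implementation of the valve law (the solver core uses
#' the identical semi-implicit update).  SI units: pressures Pa, flow m^3/s.
#'
#' @param P_up,P_down upstream/downstream pressures (Pa).
#' @param valve a [valve_params()].
#' @param state list with `zeta` (opening state) and `q` (flow m^3/s).
#' @param dt time step (s).
#' @param rho blood density (kg/m^3).
#' @return list with `q` (updated flow) and `state`.
#' @export
valve_flow <- function(P_up, P_down, valve, state = list(zeta = 0, q = 0),
                       dt, rho = 1050) {
  dP <- P_up - P_down
  if (valve$mode == "diode") {
    zeta <- as.numeric(dP > 0)
    Aeff <- max(zeta, valve$zmin) * valve$Aann
    q <- if (dP > 0) sqrt(2 * dP / rho) * Aeff else 0
    return(list(q = q, state = list(zeta = zeta, q = q)))
  }
  zeta <- state$zeta
  rate <- if (dP > 0) (1 - zeta) * valve$Kvo * dP else zeta * valve$Kvc * dP
  zeta <- min(max(zeta + dt * rate, 0), 1)
  Aeff <- max(zeta, valve$zmin) * valve$Aann
  B <- rho / (2 * Aeff^2)
  L <- rho * valve$leff / Aeff
  q <- (state$q + dt * dP / L) / (1 + dt * B * abs(state$q) / L)
  list(q = q, state = list(zeta = zeta, q = q))
}

#' Steady Bernoulli flow through a fully open valve
#'
#' Closed-form steady state of the valve law at constant positive pressure
#' gradient: \eqn{q = A_{eff}\sqrt{2\Delta P/\rho}}.
#'
#' @param dP pressure gradient (Pa), >= 0.
#' @param valve a [valve_params()].
#' @param rho blood density (kg/m^3).
#' @return flow (m^3/s).
#' @export
valve_steady_flow <- function(dP, valve, rho = 1050) {
  valve$Aann * sqrt(2 * pmax(dP, 0) / rho)
}

#' Four-chamber elastance heart
#'
#' Assembles the 0-D heart: four chambers (LA, LV, RA, RV) with the
#' elastance law of [chamber_params()], four valves (mitral, aortic,
#' tricuspid, pulmonary), an exponential pericardium
#' \eqn{P_{pc} = K\exp((V_{tot} - V_0)/\varphi)}, a lumped pulmonary circuit,
#' and the systemic venous return connections.
#'
#' Preload is controlled by the pulmonary-venous filling pressure `Pfill`
#' (the "preload clamp" that [fix_cardiac_output()] iterates on to realise
#' the Frank-Starling adjustment of LV end-diastolic volume).  With
#' `clamp = FALSE` the left atrium is instead fed by the closed pulmonary
#' compartment.
#'
#' @param hr heart rate (beats/min); cycle length is `60/hr`.
#' @param chambers named list `LA`, `LV`, `RA`, `RV` of [chamber_params()].
#' @param valves named list `mv`, `av`, `tv`, `pv` of [valve_params()].
#' @param pericardium list `K` (mmHg), `V0` (mL), `phi` (mL); `K = 0`
#'   disables the pericardial term.
#' @param Pfill pulmonary-venous filling pressure (mmHg), the preload knob.
#' @param Rfill filling resistance into the LA (mmHg s/mL).
#' @param Cpa pulmonary arterial compliance (mL/mmHg).
#' @param Rpul pulmonary resistance (mmHg s/mL).
#' @param clamp logical; `TRUE` = preload clamp (default).
#' @param venous list for the systemic venous side: `mode` ("closed" routes
#'   bed outflow through a lumped venous compartment to the RA; "open" holds
#'   a constant venous pressure), `Pven` (mmHg), `Cven` (mL/mmHg), `Rven`
#'   (mmHg s/mL).
#' @param V_init initial chamber volumes (mL), named `LA`, `LV`, `RA`, `RV`.
#' @param systole_scaling `"fraction"` (default) keeps the activation time
#'   constants a fixed fraction of the period, so ejection sharpens as the
#'   period shortens; `"sqrt"` scales them with \eqn{\sqrt{T}} instead,
#'   keeping systole closer to a fixed absolute duration.
#' @return an object of class `heart_params`.
#' @export
heart_params <- function(hr = 75,
                         chambers = list(
                           LA = chamber_params(0.45, 0.15, 4, Rs = 5e-4, Esep = 30, role = "LA"),
                           LV = chamber_params(2.5, 0.08, 20, Rs = 3e-3, Esep = 60, role = "LV"),
                           RA = chamber_params(0.30, 0.10, 4, Rs = 5e-4, Esep = 30, role = "RA"),
                           RV = chamber_params(0.55, 0.05, 15, Rs = 2e-3, Esep = 60, role = "RV")),
                         valves = list(
                           mv = valve_params(Aann = 7e-4),
                           av = valve_params(Aann = 5e-4),
                           tv = valve_params(Aann = 8e-4),
                           pv = valve_params(Aann = 5.5e-4)),
                         pericardium = list(K = 0.3, V0 = 380, phi = 90),
                         Pfill = 9.3, Rfill = 0.02,
                         Cpa = 5, Rpul = 0.06,
                         clamp = TRUE,
                         venous = list(mode = "closed", Pven = 4.5,
                                       Cven = 60, Rven = 0.006),
                         V_init = c(LA = 60, LV = 130, RA = 50, RV = 110),
                         systole_scaling = c("fraction", "sqrt")) {
  systole_scaling <- match.arg(systole_scaling)
  stopifnot(hr > 0)
  for (nm in c("LA", "LV", "RA", "RV"))
    if (!inherits(chambers[[nm]], "chamber_params"))
      stop(sprintf("heart_params: chambers$%s must be chamber_params", nm))
  structure(list(hr = hr, T = 60 / hr, chambers = chambers, valves = valves,
                 pericardium = pericardium, Pfill = Pfill, Rfill = Rfill,
                 Cpa = Cpa, Rpul = Rpul, clamp = isTRUE(clamp),
                 venous = venous, V_init = V_init,
                 systole_scaling = systole_scaling),
            class = "heart_params")
}

#' Set left-ventricular contractility
#'
#' Replaces the LV end-systolic elastance, leaving every other parameter
#' untouched.  The physiological range considered is 0.6-5.0 mmHg/mL
#' (control 2.5); values outside it trigger a warning.
#'
#' @param heart a [heart_params()].
#' @param Ees_lv new LV end-systolic elastance (mmHg/mL), > 0.
#' @return the modified `heart_params`.
#' @export
set_contractility <- function(heart, Ees_lv) {
  if (!is.numeric(Ees_lv) || length(Ees_lv) != 1L || Ees_lv <= 0)
    stop("set_contractility: Ees_lv must be a positive scalar")
  if (Ees_lv < 0.6 || Ees_lv > 5.0)
    warning(sprintf("Ees = %g mmHg/mL is outside the studied range [0.6, 5.0]",
                    Ees_lv))
  heart$chambers$LV$Ees <- Ees_lv
  heart
}

#' Set heart rate
#'
#' @param heart a [heart_params()].
#' @param hr heart rate (beats/min); the studied range is 30-180.
#' @return the modified `heart_params`.
#' @export
set_heart_rate <- function(heart, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("set_heart_rate: hr must be a positive scalar")
  if (hr < 30 || hr > 180)
    warning(sprintf("hr = %g beats/min is outside the studied range [30, 180]", hr))
  heart$hr <- hr
  heart$T <- 60 / hr
  heart
}

#' @export
print.heart_params <- function(x, ...) {
  cat(sprintf("<heart_params> HR %g bpm, LV Ees %.2f mmHg/mL (Emin %.2f, V0 %g mL)\n",
              x$hr, x$chambers$LV$Ees, x$chambers$LV$Emin, x$chambers$LV$V_P0))
  cat(sprintf("  preload: %s, Pfill %.2f mmHg; venous mode %s\n",
              if (x$clamp) "clamp" else "closed pulmonary loop",
              x$Pfill, x$venous$mode))
  invisible(x)
}
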