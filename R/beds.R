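#' Three-element Windkessel vascular bed
#'
#' A generic RCR lumped model of a microvascular bed: characteristic
#' resistance `R1` in series with a compliance `C` drained through a distal
#' resistance `R2` toward the venous reference pressure `P_out`.  The
#' compartment pressure `Pc` obeys
#' \deqn{C \frac{dP_c}{dt} = Q_{in} - (P_c - P_{out})/R_2}
#' and the pressure seen by the attached 1-D segment is
#' \eqn{P = P_c + R_1 Q_{in}}.
#'
#' The same generic bed closes every terminal of the network (no
#' organ-specific hepatic/coronary variants).
#'
#' @param R1 characteristic (proximal) resistance (Pa s/m^3).
#' @param C compliance (m^3/Pa).
#' @param R2 distal resistance (Pa s/m^3).
#' @param P_out venous reference pressure (Pa); in closed-loop simulations
#'   the venous compartment pressure replaces it at run time.
#' @param Pc initial compartment pressure (Pa).
#' @return an object of class `windkessel_bed`.
#' @export
windkessel_bed <- function(R1, C, R2, P_out = 0, Pc = P_out) {
  if (R1 <= 0 || R2 <= 0) stop("windkessel_bed: R1 and R2 must be > 0")
  if (C <= 0) stop("windkessel_bed: C must be > 0")
  structure(list(R1 = R1, C = C, R2 = R2, P_out = P_out, Pc = Pc),
            class = "windkessel_bed")
}

#' Advance a Windkessel bed one time step
#'
#' Semi-implicit (backward Euler in the compartment pressure) update of the
#' RCR bed given the inflow over the step.
#'
#' @param bed a [windkessel_bed()].
#' @param Q_in inflow from the 1-D side (m^3/s), taken constant over the step.
#' @param dt step size (s), > 0.
#' @return a list with `P` (interface pressure, Pa), `Q_out` (outflow through
#'   `R2`, m^3/s) and `bed` (bed with updated state).
#' @export
bed_step <- function(bed, Q_in, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("bed_step: dt must be > 0")
  tau <- bed$R2 * bed$C
  Pc_new <- (bed$Pc + dt / bed$C * (Q_in + bed$P_out / bed$R2)) / (1 + dt / tau)
  bed$Pc <- Pc_new
  list(P = Pc_new + bed$R1 * Q_in,
       Q_out = (Pc_new - bed$P_out) / bed$R2,
       bed = bed)
}

#' Input impedance modulus of an RCR bed
#'
#' Analytic frequency response \eqn{|Z(\omega)| = |R_1 + R_2/(1 + j\omega R_2 C)|}
#' used as an oracle for the time-domain update.
#'
#' @param bed a [windkessel_bed()].
#' @param omega angular frequency (rad/s), vector allowed.
#' @return impedance modulus (Pa s/m^3).
#' @export
bed_impedance <- function(bed, omega) {
  Mod(bed$R1 + bed$R2 / (1 + 1i * omega * bed$R2 * bed$C))
}

#' Match a bed's proximal resistance to the vessel's characteristic impedance
#'
#' Sets \eqn{R_1 = \rho c_0 / A_d} evaluated at the attached segment end, the
#' standard choice that minimises spurious reflections of incident waves at
#' the terminal.
#'
#' @param bed a [windkessel_bed()].
#' @param seg the terminal [vessel_segment()].
#' @param end which end is attached, `"prox"` or `"dist"`.
#' @param fluid a [fluid_properties()].
#' @param preserve_total if `TRUE` (default), `R2` is adjusted so that
#'   `R1 + R2` (the DC resistance against `P_out`) is unchanged.
#' @return the bed with `R1` (and possibly `R2`) updated.
#' @export
match_characteristic_impedance <- function(bed, seg, end = "dist",
                                           fluid = fluid_properties(),
                                           preserve_total = TRUE) {
  x <- if (end == "prox") 0 else seg$L
  Ad <- segment_Ad(seg, x)
  c0 <- wave_speed(Ad, x, seg, fluid)
  Rtot <- bed$R1 + bed$R2
  bed$R1 <- fluid$rho * c0 / Ad
  if (preserve_total) {
    R2 <- Rtot - bed$R1
    if (R2 <= 0)
      stop("match_characteristic_impedance: characteristic impedance exceeds total bed resistance")
    bed$R2 <- R2
  }
  bed
}

#' Rescale every bed's resistance
#'
#' Multiplies `R1` and `R2` of all Windkessel terminals by a common factor
#' (keeping each bed's compliance), the global afterload knob used for
#' cardiac-output tuning and afterload-variation experiments.
#'
#' @param net a [network_spec()].
#' @param factor positive multiplier on the bed resistances.
#' @return the modified `network_spec`.
#' @export
scale_bed_resistance <- function(net, factor) {
  if (!is.numeric(factor) || factor <= 0)
    stop("scale_bed_resistance: factor must be > 0")
  for (i in seq_along(net$terminals)) {
    tm <- net$terminals[[i]]
    if (tm$type == "windkessel") {
      tm$bed$R1 <- tm$bed$R1 * factor
      tm$bed$R2 <- tm$bed$R2 * factor
      net$terminals[[i]] <- tm
    }
  }
  net
}

#' @export
print.windkessel_bed <- function(x, ...) {
  cat(sprintf("<windkessel_bed> R1=%.3g C=%.3g R2=%.3g P_out=%.3g (SI)\n",
              x$R1, x$C, x$R2, x$P_out))
  invisible(x)
}
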