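---
title: "A closed-loop 1-D pulse wave model of heart-aorta-brain coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop 1-D pulse wave model of heart-aorta-brain coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hemowave` simulates pulse wave propagation through a closed circulatory
loop — a four-chamber time-varying elastance heart driving a network of
one-dimensional nonlinear vessel segments terminated by three-element
Windkessel vascular beds — and post-processes the converged cycle into the
indices used to quantify pulsatile energy transmission from the left
ventricle, through the aorta, to the brain: carotid pulsatile power, wave
intensity and wave power, wave separation and reflection index, flow
pulsatility index, and cerebral blood flow.  This vignette records the
model equations, the numerical choices and their rationale, what the
packaged synthetic arterial tree does and does not emulate, and the
package's known limitations.

## The 1-D vessel model

Each vessel segment carries cross-sectional area $A(x,t)$ and
cross-section-averaged axial velocity $U(x,t)$ (flow $Q = AU$), governed by

$$
\partial_t A = -\partial_x (AU), \qquad
\partial_t U = -U\,\partial_x U - \frac{1}{\rho}\,\partial_x P
              - \frac{2(\xi + 2)\pi\mu\,U}{\rho A},
$$

with constant blood density $\rho$ and viscosity $\mu$, and a
velocity-profile constant $\xi$ in the wall-friction term.  The default
$\xi = 9$ corresponds to a flat-core profile and yields the
$22\pi\mu U/(\rho A)$ friction conventionally used for large arteries
($\xi = 2$ would give Poiseuille friction); it is a `fluid_properties()`
field because the literature is not unanimous.

The system is closed by the elastic tube law

$$
P(A, x) = P_{ext} + \frac{\beta(x)}{A_d(x)}
          \left(\sqrt{A} - \sqrt{A_d(x)}\right),
\qquad
\beta = \tfrac{4}{3}\sqrt{\pi}\,E\,h,
$$

where $A_d$ is the diastolic area, $E$ the elastic modulus and $h$ the
wall thickness.  $P_{ext}$ is the reference pressure at which the section
sits at its diastolic area; the packaged fixtures set it to 80 mmHg so
that the initial condition ($A = A_d$, $U = 0$) is a diastolic state and
the start-up transient is short.  Both $A_d$ and $\beta$ taper linearly in
$x$ between proximal and distal values — the common choice in 1-D
modelling when only end diameters are tabulated.  The local wave speed is
$c = \sqrt{\beta\sqrt{A}/(2\rho A_d)}$, reducing at the diastolic area to
$c_0 = \sqrt{\beta/(2\rho\sqrt{A_d})}$; `scale_aortic_stiffness(net, m)`
multiplies $\beta$ of the designated aortic subset by $m^2$ so the aortic
pulse wave velocity (PWV) scales by exactly $m$.

At junctions (two or more attached ends; bifurcations and trifurcations
are both used) the solver enforces continuity of total pressure
$P + \rho U^2/2$ and conservation of mass, with flows oriented into the
junction summing to zero, while preserving each vessel's outgoing
characteristic invariant.

## Numerics

The interior scheme is an alternating-direction MacCormack
predictor-corrector: second order in space and time on smooth solutions,
cheap per step, and adequate for physiological (shock-free) wave
amplitudes.  Three numerical details matter and are worth recording:

* **Boundary closures.**  Every segment end is closed each step by
  combining the outgoing Riemann invariant $W_\pm = U \pm 4c$ — traced to
  the foot of its characteristic with quadratic interpolation — with the
  boundary condition (junction system, Windkessel bed, valve/heart flow,
  or a closed end).  Two refinements proved essential rather than
  cosmetic.  First, the friction and geometric-taper source terms of the
  invariant are integrated along the characteristic path; without them
  the closure is only first-order accurate and the committed boundary
  fluxes acquire a small systematic bias that, accumulated over a dozen
  segment ends, destroyed a few percent of the mean flow between the
  aortic valve and the terminal beds.  Second, the closure and the
  dissipation filter (below) operate on pressure/velocity rather than raw
  area, because on a tapered vessel the equilibrium area profile is
  curved in $x$ and differencing it directly manufactures spurious wave
  content (the closure must be *well balanced*: a tapered vessel at rest
  must remain exactly at rest).

* **Dissipation filter.**  Node-coupled boundary closures can excite a
  standing two-grid-point mode to which MacCormack is neutrally stable.
  A weak filter (4th-difference in the interior, 2nd-difference at the
  two near-boundary nodes, strength 0.05) removes it without affecting
  the observed convergence order; both strengths are `solver_config()`
  fields and 0 disables them.

* **Junction Newton solves.**  The coupled junction system is solved by
  Newton iteration with an analytic Jacobian to a relative residual of
  $10^{-14}$ (with a no-progress escape below $10^{-12}$); the committed
  states satisfy mass conservation to well below $10^{-12}$ of the flow
  scale at every step.

Time steps follow a CFL condition (default Courant number 0.7 against an
estimated systolic wave speed).  Cycles repeat until the pressure at every
monitored site differs from the previous cycle by less than a relative
L2 tolerance (default $10^{-3}$; the experiment driver uses
$2\times10^{-4}$), and the last cycle is resampled at 1 kHz for analysis
independently of the solver step.  All internal quantities are strict SI;
mmHg, mL and L/min appear only at the interfaces (1 mmHg = 133.322 Pa).

## The elastance heart

Chamber pressure follows the time-varying elastance law

$$
P = P_{pc} + \frac{E_{nat}}{E_{sep}}P^{*}
    + E_{nat}(t)\,(V - V_{P=0}) - R_s\,q,
\qquad
E_{nat}(t) = E_{min} + e(t)\,(E_{es} - E_{min}),
$$

with pericardial pressure $P_{pc} = K\exp((V_{tot} - V_0)/\varphi)$
monotone in the total four-chamber volume, a septal coupling to the
contralateral chamber pressure $P^{*}$ (taken explicitly from the
previous solver substep; $E_{sep} = \infty$ decouples), and a source
resistance $R_s$ on the chamber outflow.  Ventricular activation $e(t)$
is the normalized double-Hill waveform; the atria contract in late
diastole with a raised-sine bump.  Valves follow a pressure-gradient
driven opening-state ODE with Bernoulli resistance and blood inertance
through the effective open area (an ideal-diode mode exists for
debugging).  The LV end-systolic elastance $E_{es}$ is the contractility
index: 2.5 mmHg/mL is the control value, with 0.6–5.0 the studied range.

**Activation timing across heart rates.**  How systole scales with the
period $T$ is not dictated by the chamber law, and the package makes it a
switch (`systole_scaling`).  The default keeps the activation time
constants a *fixed fraction* of $T$, so ejection sharpens as the period
shortens; the alternative scales them with $\sqrt{T}$, keeping systole
closer to a fixed absolute duration.  The fraction default was chosen
because it reproduces the reported behaviour of this model family at
fixed cardiac output: forward compression wave intensity and wave power
*rise* with heart rate, which requires peak ejection rate to be
maintained as $T$ falls; under $\sqrt{T}$ scaling every pulsatility index
simply collapses with heart rate and the high-rate behaviour of the
system is lost.

**Preload control.**  The Frank-Starling adjustment used to isolate
contractility effects from flow effects is implemented as a preload
clamp: the left atrium fills from a constant pulmonary-venous pressure
`Pfill`, and `fix_cardiac_output()` (or `fix_lvedv()`) secant-iterates on
that single knob until the converged cycle delivers the target cardiac
output (or end-diastolic volume).  Bed outflow still returns through a
lumped venous compartment to the right atrium, so the right heart runs in
a closed loop; the clamp sits between the pulmonary compartment and the
left atrium.  A fully closed pulmonary loop (`clamp = FALSE`) is
available, in which case preload must be controlled through total volume.

## Windkessel beds

Each terminal couples to a three-element (RCR) bed: proximal resistance
$R_1$, compliance $C$ drained through $R_2$ toward the venous pressure;
the same generic bed closes every outlet (no organ-specific hepatic or
coronary variants).  `match_characteristic_impedance()` sets
$R_1 = \rho c_0/A_d$ of the attached vessel end, which minimises spurious
terminal reflections and is the right choice for solver verification
fixtures.  The compartment update is semi-implicit and unconditionally
stable at the solver step.

## The packaged reduced tree

`make_reduced_tree()` builds the study fixture: a tapered aorta
(ascending, two arch pieces, thoracic, abdominal — the stiffness-scaled
"aortic" subset), brachiocephalic, both common carotids, both
subclavian/vertebral/brachial branches; four cerebral beds (carotids,
vertebrals), two arm beds, and one lumped lower-body bed; the ascending
aorta is driven by the heart.  Calibration is analytic and part of the
generator: aortic $\beta$ values give a diastolic aortic PWV of exactly
4.66 m/s; bed resistances are sized so a design flow split (5% of cardiac
output per carotid, 1.6% per vertebral, 8.6% per arm, remainder to the
lower body — a 13.2% cerebral fraction) adds up to 5.6 L/min at a mean
pressure of 93 mmHg; and the default heart delivers that output with an
LV end-diastolic volume near 136 mL (ejection fraction ≈ 55%).

Three fixture parameters encode physiology that a 14-segment tree would
otherwise lack, and were fixed during model validation against the
reported qualitative behaviour of the full-scale model family:

* the four **cerebral beds** use a short drainage time constant
  ($R_2C = 0.25$ s, versus 1.3 s for the systemic beds), matching the
  cerebrovascular time constant of roughly 0.2–0.3 s measured in healthy
  adults; stiff distal beds make carotid flow track pressure instead of
  being buffered away;
* the **lower-body bed** sets $R_1$ to twice the characteristic impedance
  of the distal aorta, reproducing the effective aorto-iliac reflection
  site (high-frequency reflection coefficient ≈ 1/3) that the truncated
  lower body removes — the dominant timed reflection in the systemic
  circulation;
* **activation timing** defaults to fraction-of-period scaling as
  discussed above.

With these choices the fixture reproduces, qualitatively: the carotid
wave-intensity pattern (a dominant early-systolic forward compression
peak, a backward compression trough, a late-systolic forward expansion
peak, in that order); a dicrotic notch in root pressure at aortic valve
closure; rising carotid pulsatile power and pulsatility with
contractility at fixed cardiac output while the steady power stays within
2%; monotonically increasing pulsatile power with aortic stiffness;
falling cerebral blood flow with stiffness at fixed preload; and a
carotid pulsatile power vs. heart rate curve with an interior minimum.
On the coarse grid {30, 50, 75, 100, 125} beats/min the minimum sits at
50 beats/min for stiffness multiples 1 and 3 and at 75 for multiple 2 —
at or one grid point below the normal-heart-rate optimum of the
full-scale model.  The location of that minimum is set by the interference
timing of the (single) lower-body reflection, and a 14-segment tree with
one discrete reflection site cannot be expected to pin it exactly; the
*existence* of an interior optimum and every monotonicity above are the
properties the fixture is designed to exhibit.  Quantitative index values
(mW-scale powers, index magnitudes) belong to the full 122-artery/162-vein
parameterisation, which users can supply through the network file format;
the packaged tree is a clearly-labelled synthetic stand-in.

What passing tests on this fixture do **not** show about real data: no
venous wave propagation (the venous return is lumped), no cerebral
autoregulation (deliberately excluded — the model quantifies the load the
autoregulation would face), no viscoelastic wall damping (pulse pressures
at the periphery are therefore slightly over-peaked), and no distributed
minor branching, so reflection spectra are sparser than in vivo.

## Analysis layer conventions

All metrics are computed on one uniformly sampled converged cycle
(means are plain sample means; the grid covers $[0, T)$ without a
duplicated endpoint, so trapezoidal integration of the periodic signal
reduces to the mean).

* **Power decomposition**: $\bar P_{total} = \frac{1}{T}\int PQ\,dt$,
  $\bar P_s = P_{mean}Q_{mean}$, and the carotid pulsatile power
  $CPP = \bar P_{total} - \bar P_s$, exactly by construction.
* **Wave intensity**: $dI = (dP/dt)(dU/dt)$ from centred differences at
  1 kHz with no smoothing by default (solver output is smooth; a
  Savitzky-Golay option exists for external data).  Peaks are picked by
  quadrant: FCWI on the joint upstroke ($dP, dU > 0$), FEWI on the joint
  late-systolic decay ($dP, dU < 0$), BCWI as the (positive) magnitude of
  the trough between them.
* **Wave power**: the pulsatile product
  $WP = (P - P_{mean})(Q - Q_{mean})$, with FCWP the first systolic peak
  located on the joint pressure/flow upstroke.  The product of raw $P$
  and $Q$ is the other convention in circulation; the pulsatile product
  was chosen because it vanishes for steady flow and its peak is
  co-timed with FCWI.
* **Wave separation**: $dP_f = (dP + \rho c\,dU)/2$,
  $dP_b = (dP - \rho c\,dU)/2$, cumulatively summed, de-drifted and
  anchored so $P_f + P_b = P$ exactly with the mean carried by the
  forward component.  The site wave speed is the diastolic $c_0$
  (single-point estimate); PU-loop alternatives are deliberately not the
  default because they fail when forward and backward waves overlap.
* **Reflection index**: backward-to-total *amplitude* ratio
  (peak-to-trough), in percent — the default convention; a peak-deviation
  convention is provided because the verbal definition ("peak backward
  pressure over the total pressure") is ambiguous.
* **Pulsatility index**: $(q_{max} - q_{min})/\bar q$.
* **Cerebral blood flow**: the sum of cycle-mean flow over both carotids
  and both vertebrals, with percent change against the baseline-stiffness
  run of the same heart settings.

## Experiment driver

`run_sweep()` crosses contractility, heart rate and aortic PWV multiple.
In fixed-CO mode every grid point re-runs `fix_cardiac_output()` (1%
tolerance); in fixed-LVEDV mode the first stiffness level of each
(contractility, heart-rate) slice defines the reference end-diastolic
volume and later levels clamp to it via `fix_lvedv()` — holding the
filling pressure instead would let the end-diastolic volume creep up with
afterload and Frank-Starling away part of the cerebral-flow response.
Bed resistances are held fixed when heart rate changes, so mean pressure
varies along the heart-rate axis unless CO-fixing is on; this matches the
separate fixed-preload and fixed-output designs the analysis
distinguishes.  The model has no stochastic elements: repeated sweeps are
bit-identical, and non-convergent grid points are recorded and skipped,
not fatal.

Problem sizes used by the packaged experiments and the test suite — a
14-segment tree with roughly 150 nodes, 1.5–10 ms periods resolved with
1500–6000 steps per cycle, 10–40 cycles to periodicity, and sweeps of up
to 15 grid points with preload iteration — were chosen so the full
acceptance battery reproduces the study's qualitative findings in a few
minutes on one core while keeping every verification oracle (convergence
order, reflection coefficients, conservation residuals) comfortably
resolved.

## Known limitations

Elastic (not viscoelastic) walls; generic beds everywhere (no hepatic or
coronary specialisation); lumped venous return rather than 162 venous
segments; no autoregulatory feedback; no shock capturing (physiological
amplitudes only); explicit septal coupling (adequate at the solver's
small steps); and the reduced tree's sparse reflection spectrum discussed
above.  The network file format is the intended route to the full-scale
parameterisation when quantitative reproduction is required.
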