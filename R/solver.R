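#' Solver configuration
#'
#' @param cfl Courant number used to pick the time step from the grid spacing
#'   and an estimate of the fastest characteristic speed (the MacCormack
#'   scheme is stable up to 1; the default leaves margin for systolic wave
#'   speeds).
#' @param dt explicit time step (s); overrides `cfl` when given.
#' @param cycles_max maximum number of cardiac cycles to run.
#' @param tol periodicity tolerance: the run stops once the relative L2
#'   difference between successive cycles' pressure at every monitored site
#'   falls below `tol`.
#' @param min_steps minimum solver steps per cycle.
#' @param n_out number of uniform output samples per cycle; `NULL` gives
#'   1 kHz sampling (`round(1000 T)`), independent of the solver step.
#' @param record_heart record 0-D heart traces for the final cycle.
#' @param eps4,eps2 strengths of the weak dissipation filter applied each
#'   step (4th-difference in the segment interior, 2nd-difference at the
#'   two near-boundary nodes, acting on pressure and velocity).  It damps
#'   the two-grid-point odd-even mode that node-coupled boundary closures
#'   can excite while leaving smooth solutions at the scheme's formal
#'   order; 0 disables it.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(cfl = 0.7, dt = NULL, cycles_max = 40L, tol = 1e-3,
                          min_steps = 400L, n_out = NULL, record_heart = TRUE,
                          eps4 = 0.05, eps2 = 0.05) {
  if (!is.null(dt) && dt <= 0) stop("solver_config: dt must be > 0")
  if (tol <= 0) stop("solver_config: tol must be > 0")
  structure(list(cfl = cfl, dt = dt, cycles_max = as.integer(cycles_max),
                 tol = tol, min_steps = as.integer(min_steps),
                 n_out = n_out, record_heart = isTRUE(record_heart),
                 eps4 = eps4, eps2 = eps2),
            class = "solver_config")
}

## --- flattening helpers ------------------------------------------------

.seg_index <- function(net) {
  ids <- vapply(net$segments, function(s) s$id, character(1))
  stats::setNames(seq_along(ids) - 1L, ids)  # 0-based for C++
}

.flatten_network <- function(net, init_segs = NULL, closed_loop = TRUE,
                             inflow_tab = NULL) {
  idx <- .seg_index(net)
  segs <- lapply(seq_along(net$segments), function(i) {
    s <- net$segments[[i]]
    x <- segment_x(s)
    Ad <- segment_Ad(s, x)
    beta <- segment_beta(s, x)
    if (!is.null(init_segs)) {
      A0 <- init_segs[[i]]$A; U0 <- init_segs[[i]]$U
      if (length(A0) != s$n_nodes)
        stop("simulate_circulation: initial state does not match segment '",
             s$id, "' resolution")
    } else {
      A0 <- Ad; U0 <- rep(0, s$n_nodes)
    }
    list(n = s$n_nodes, dx = s$L / (s$n_nodes - 1L), Pext = s$Pext,
         Ad = Ad, beta = beta, A0 = A0, U0 = U0)
  })
  juncs <- lapply(net$junctions, function(j) {
    ends <- c(j$parents, j$daughters)
    list(seg = vapply(ends, function(e) idx[[e$segment]], integer(1)),
         end = vapply(ends, function(e) if (e$end == "dist") 1L else 0L,
                      integer(1)))
  })
  type_code <- c(windkessel = 0L, closed = 1L, heart = 2L, inflow = 3L)
  terms <- lapply(net$terminals, function(tm) {
    ty <- tm$type
    if (ty == "heart" && !is.null(inflow_tab)) ty <- "inflow"
    out <- list(seg = idx[[tm$segment]],
                end = if (tm$end == "dist") 1L else 0L,
                type = type_code[[ty]],
                R1 = 1, C = 1, R2 = 1, Pout = 0, Pc = 0,
                to_venous = FALSE)
    if (ty == "windkessel") {
      out$R1 <- tm$bed$R1; out$C <- tm$bed$C; out$R2 <- tm$bed$R2
      out$Pout <- tm$bed$P_out; out$Pc <- tm$bed$Pc
      out$to_venous <- isTRUE(closed_loop)
    }
    if (ty == "inflow") out$Qtab <- inflow_tab
    out
  })
  list(segs = segs, junctions = juncs, terminals = terms,
       rho = net$fluid$rho, mu = net$fluid$mu, xi = net$fluid$xi)
}

.E_SI <- MMHG_PA / ML_M3     # mmHg/mL -> Pa/m^3 (also mmHg s/mL -> Pa s/m^3)
.C_SI <- ML_M3 / MMHG_PA     # mL/mmHg -> m^3/Pa

.flatten_heart <- function(heart, n_steps, dt, init_state = NULL) {
  T <- heart$T
  tgrid <- (seq_len(n_steps) - 1L) * dt
  if (heart$systole_scaling == "sqrt") {
    ev <- activation_double_hill(tgrid, T)
    ea <- activation_atrial(tgrid, T)
  } else {
    ev <- activation_double_hill(tgrid, T, tau1 = 0.269 * T, tau2 = 0.452 * T)
    ea <- activation_atrial(tgrid, T, dur = 0.2 * T)
  }
  ch <- lapply(heart$chambers[c("LA", "LV", "RA", "RV")], function(c.)
    list(Ees = c.$Ees * .E_SI, Emin = c.$Emin * .E_SI,
         V0 = c.$V_P0 * ML_M3, Rs = c.$Rs * .E_SI,
         Esep = if (is.finite(c.$Esep)) c.$Esep * .E_SI else -1))
  vv <- lapply(heart$valves[c("mv", "av", "tv", "pv")], function(v)
    list(Aann = v$Aann, leff = v$leff, Kvo = v$Kvo, Kvc = v$Kvc,
         zmin = v$zmin))
  if (is.null(init_state)) {
    st <- numeric(19)
    st[1:4] <- heart$V_init[c("LA", "LV", "RA", "RV")] * ML_M3
    st[13] <- 15 * MMHG_PA                        # Ppa
    st[14] <- 0                                   # Vven offset handled below
    st[15] <- 80 * MMHG_PA                        # P_root guess
    st[16:19] <- c(8, 10, 5, 8) * MMHG_PA         # previous chamber pressures
  } else st <- init_state
  venous_closed <- identical(heart$venous$mode, "closed")
  Vven0 <- 0.0  # venous volume tracked as offset from the reference state
  list(chambers = ch, valves = vv,
       Kpc = heart$pericardium$K * MMHG_PA,
       Vpc0 = heart$pericardium$V0 * ML_M3,
       phipc = heart$pericardium$phi * ML_M3,
       Cpa = heart$Cpa * .C_SI, Rpul = heart$Rpul * .E_SI,
       Rfill = heart$Rfill * .E_SI, Pfill = heart$Pfill * MMHG_PA,
       clamp = heart$clamp,
       Cven = heart$venous$Cven * .C_SI, Vven0 = Vven0,
       Rven = heart$venous$Rven * .E_SI,
       Pven_ref = heart$venous$Pven * MMHG_PA,
       venous_closed = venous_closed,
       ev = ev, ea = ea, state = st)
}

.pick_dt <- function(net, T, config) {
  if (!is.null(config$dt)) {
    n_steps <- max(config$min_steps, ceiling(T / config$dt))
    return(list(dt = T / n_steps, n_steps = as.integer(n_steps)))
  }
  dtmax <- Inf
  for (s in net$segments) {
    x <- segment_x(s)
    c0 <- wave_speed(segment_Ad(s, x), x, s, net$fluid)
    c_est <- 1.4 * max(c0) + 2.0   # systolic speed + advective margin
    dx <- s$L / (s$n_nodes - 1L)
    dtmax <- min(dtmax, dx / c_est)
  }
  n_steps <- max(config$min_steps, ceiling(T / (config$cfl * dtmax)))
  list(dt = T / n_steps, n_steps = as.integer(n_steps))
}

.default_sites <- function(net) {
  sites <- list()
  for (tm in net$terminals) {
    if (tm$type %in% c("heart", "inflow")) {
      sites[[length(sites) + 1L]] <-
        list(segment = tm$segment, pos = 0, name = "root")
    } else {
      sites[[length(sites) + 1L]] <-
        list(segment = tm$segment, pos = 0.5, name = tm$segment)
    }
  }
  sites
}

## periodic linear resampling of a cycle sampled at n points onto m points
.resample_cycle <- function(v, m) {
  n <- length(v)
  if (n == m) return(v)
  pos <- (seq_len(m) - 1L) / m * n          # fractional index in [0, n)
  i0 <- floor(pos)
  fr <- pos - i0
  i0 <- as.integer(i0 %% n) + 1L
  i1 <- as.integer(i0 %% n) + 1L
  (1 - fr) * v[i0] + fr * v[i1]
}

#' Simulate the circulation to a periodic limit cycle
#'
#' Runs the coupled 1-D network / 0-D heart / Windkessel-bed model over
#' repeated cardiac cycles until the pressure waveform at every monitored
#' site differs from the previous cycle by less than `config$tol` in
#' relative L2 norm, then returns the converged cycle sampled uniformly
#' (1 kHz by default).
#'
#' The inlet is driven either by the four-chamber elastance heart (`heart`
#' given; the network must contain a terminal of type `"heart"`) or by a
#' prescribed periodic inflow (`inflow` given as a function of time or a
#' sampled vector over one period).
#'
#' @param net a [network_spec()].
#' @param heart a [heart_params()], or `NULL` for heartless fixtures.
#' @param inflow prescribed inlet flow (m^3/s): function of time on
#'   \eqn{[0, T)} or numeric vector sampled uniformly over one period.
#'   Replaces the heart at the `"heart"` terminal.
#' @param T cycle length (s); defaults to the heart's `60/hr`, required when
#'   only `inflow` is given.
#' @param config a [solver_config()].
#' @param sites monitored sites: list of `list(segment =, pos =, name =)`
#'   with `pos` the fractional position from the proximal end (0-1).
#'   Defaults to the midpoint of every bed-terminated segment plus the inlet
#'   root.
#' @param init initial state: `NULL` (diastolic rest), a previous `circ_sim`
#'   (restart from its final state), or a raw state list with elements
#'   `segs`, `bedPc`, `heart`.
#' @param closed_loop route bed outflow through the lumped venous compartment
#'   to the right atrium (only meaningful with a heart whose venous mode is
#'   `"closed"`).
#' @return an object of class `circ_sim`: named list of
#'   [waveform_record()]s (`records`), heart traces (`heart_trace`,
#'   clinical units), cardiac output `co` (L/min), `lvedv` (mL), convergence
#'   metadata and the final solver `state` for restarts.
#' @export
simulate_circulation <- function(net, heart = NULL, inflow = NULL, T = NULL,
                                 config = solver_config(), sites = NULL,
                                 init = NULL, closed_loop = TRUE) {
  stopifnot(inherits(net, "network_spec"))
  if (is.null(heart) && is.null(inflow)) {
    if (is.null(T)) stop("simulate_circulation: need heart, inflow or T")
  }
  if (!is.null(heart) && !inherits(heart, "heart_params"))
    stop("simulate_circulation: heart must be heart_params")
  if (is.null(T)) T <- if (!is.null(heart)) heart$T else
    stop("simulate_circulation: T required with a prescribed inflow")
  ts <- .pick_dt(net, T, config)

  inflow_tab <- NULL
  if (!is.null(inflow)) {
    inflow_tab <- if (is.function(inflow))
      inflow((seq_len(ts$n_steps) - 1L) * ts$dt) else as.numeric(inflow)
    if (anyNA(inflow_tab)) stop("simulate_circulation: inflow produced NA")
  }

  init_state <- NULL
  if (inherits(init, "circ_sim")) init_state <- init$state
  else if (is.list(init) && !is.null(init$segs)) init_state <- init

  flat <- .flatten_network(net,
                           init_segs = init_state$segs,
                           closed_loop = closed_loop && !is.null(heart) &&
                             identical(heart$venous$mode, "closed"),
                           inflow_tab = inflow_tab)
  if (!is.null(init_state$bedPc)) {
    k <- 0L
    for (i in seq_along(flat$terminals)) {
      k <- k + 1L
      flat$terminals[[i]]$Pc <- init_state$bedPc[k]
    }
  }

  use_heart <- !is.null(heart) && is.null(inflow_tab)
  heartL <- if (use_heart)
    .flatten_heart(heart, ts$n_steps, ts$dt, init_state$heart) else list()
  if (use_heart &&
      !any(vapply(net$terminals, function(tm) tm$type == "heart", logical(1))))
    stop("simulate_circulation: network has no 'heart' terminal for the aortic root")

  if (is.null(sites)) sites <- .default_sites(net)
  idx <- .seg_index(net)
  mon_seg <- integer(0); mon_node <- integer(0); mon_name <- character(0)
  mon_x <- numeric(0)
  for (st in sites) {
    s <- net$segments[[st$segment]]
    if (is.null(s)) stop("simulate_circulation: unknown site segment '",
                         st$segment, "'")
    node <- round(st$pos * (s$n_nodes - 1L))
    mon_seg <- c(mon_seg, idx[[st$segment]])
    mon_node <- c(mon_node, as.integer(node))
    mon_name <- c(mon_name, st$name %||% st$segment)
    mon_x <- c(mon_x, node * s$L / (s$n_nodes - 1L))
  }

  cfg <- list(dt = ts$dt, n_steps = ts$n_steps,
              cycles_max = config$cycles_max, tol = config$tol,
              mon_seg = mon_seg, mon_node = mon_node,
              record_heart = config$record_heart && use_heart,
              eps4 = config$eps4, eps2 = config$eps2)
  out <- .cpp_simulate(flat, heartL, cfg)

  n_out <- config$n_out %||% max(64L, round(1000 * T))
  t_out <- (seq_len(n_out) - 1L) * T / n_out
  records <- list()
  for (m in seq_along(mon_name)) {
    A <- .resample_cycle(out$A[, m], n_out)
    U <- .resample_cycle(out$U[, m], n_out)
    P <- .resample_cycle(out$P[, m], n_out)
    records[[mon_name[m]]] <- waveform_record(
      t = t_out, P = P, Q = A * U, U = U, A = A, site = mon_name[m])
  }

  heart_trace <- NULL
  if (cfg$record_heart && nrow(out$heart) > 0) {
    H <- out$heart
    heart_trace <- data.frame(
      t = (seq_len(ts$n_steps) - 1L) * ts$dt,
      V_LA = H[, 1] / ML_M3, V_LV = H[, 2] / ML_M3,
      V_RA = H[, 3] / ML_M3, V_RV = H[, 4] / ML_M3,
      P_LA = H[, 5] / MMHG_PA, P_LV = H[, 6] / MMHG_PA,
      P_RA = H[, 7] / MMHG_PA, P_RV = H[, 8] / MMHG_PA,
      q_mv = H[, 9] / ML_M3, q_av = H[, 10] / ML_M3,
      P_root = H[, 11] / MMHG_PA, P_pa = H[, 12] / MMHG_PA,
      P_ven = H[, 13] / MMHG_PA, zeta_av = H[, 14])
  }

  nc <- out$cycles
  structure(list(
    records = records,
    heart_trace = heart_trace,
    co = if (use_heart && length(out$co)) out$co[nc] / LMIN_M3S else NA_real_,
    lvedv = if (use_heart && length(out$lvedv)) out$lvedv[nc] / ML_M3 else NA_real_,
    converged = out$converged,
    cycles = nc,
    residuals = out$residuals,
    co_history = out$co / LMIN_M3S,
    arterial_volume = out$arterial_volume,
    junction_mass_residual = out$junction_mass_residual,
    state = out$state,
    T = T, dt = ts$dt, n_steps = ts$n_steps,
    hr = if (!is.null(heart)) heart$hr else 60 / T,
    config = config), class = "circ_sim")
}

#' Run a configuration to its periodic limit cycle
#'
#' Thin wrapper over [simulate_circulation()] that errors if the periodicity
#' tolerance was not reached within `config$cycles_max` cycles, returning the
#' converged cycle otherwise.
#'
#' @inheritParams simulate_circulation
#' @param ... passed to [simulate_circulation()].
#' @return a `circ_sim` (see [simulate_circulation()]).
#' @export
run_to_periodic <- function(net, heart = NULL, config = solver_config(), ...) {
  sim <- simulate_circulation(net, heart = heart, config = config, ...)
  if (!sim$converged) {
    stop(sprintf(paste0("run_to_periodic: no periodic limit cycle within %d ",
                        "cycles (last residual %.3g, tol %.3g)"),
                 sim$cycles, utils::tail(sim$residuals, 1), config$tol))
  }
  sim
}

#' Advance the model by exactly one cardiac period
#'
#' Runs a single cycle from the given initial state (no periodicity check);
#' useful for step-by-step studies and conservation tests.
#'
#' @inheritParams simulate_circulation
#' @param ... passed to [simulate_circulation()].
#' @return a `circ_sim` after one period.
#' @export
advance_cycle <- function(net, heart = NULL, config = solver_config(),
                          init = NULL, ...) {
  config$cycles_max <- 1L
  simulate_circulation(net, heart = heart, config = config, init = init, ...)
}

#' Interior right-hand side of the 1-D equations
#'
#' Reference evaluation of the time derivatives of (A, U) for a vessel
#' state, using centred differences in the interior and one-sided
#' differences at the ends:
#' \deqn{\partial_t A = -\partial_x(AU), \qquad
#'       \partial_t U = -U\partial_x U - \frac{1}{\rho}\partial_x P
#'                      - \frac{2(\xi+2)\pi\mu U}{\rho A}.}
#'
#' @param A,U nodal areas (m^2) and velocities (m/s), length `seg$n_nodes`.
#' @param seg a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return list with `dA_dt` and `dU_dt`.
#' @export
rhs_interior <- function(A, U, seg, fluid) {
  if (any(A <= 0)) stop("rhs_interior: nonpositive area (diverged state)")
  n <- seg$n_nodes
  stopifnot(length(A) == n, length(U) == n)
  x <- segment_x(seg)
  dx <- x[2] - x[1]
  P <- tube_law_pressure(A, x, seg)
  ddx <- function(v) {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dx)
    d[1] <- (v[2] - v[1]) / dx
    d[n] <- (v[n] - v[n - 1]) / dx
    d
  }
  fric <- 2 * (fluid$xi + 2) * pi * fluid$mu * U / (fluid$rho * A)
  list(dA_dt = -ddx(A * U),
       dU_dt = -U * ddx(U) - ddx(P) / fluid$rho - fric)
}

#' Couple segment ends at a junction
#'
#' Reference (R-level) Newton solve of the junction conditions: given the
#' current state at each attached end, finds boundary values that preserve
#' each vessel's outgoing characteristic invariant while enforcing equal
#' total pressure \eqn{P + \rho U^2/2} and zero signed mass flux
#' (flows oriented into the junction are positive).  The solver core applies
#' the same conditions each step.
#'
#' @param ends list of attached ends, each
#'   `list(seg = <vessel_segment>, end = "prox"|"dist", A =, U =)`.
#' @param fluid a [fluid_properties()].
#' @param tol residual tolerance (relative).
#' @return list of boundary states `list(A, U, P)` per end, with attributes
#'   `mass_residual` and `pressure_residual`.
#' @export
solve_junction <- function(ends, fluid, tol = 1e-12) {
  m <- length(ends)
  if (m < 2L) stop("solve_junction: need at least two attached ends")
  rho <- fluid$rho
  node_x <- vapply(ends, function(e) if (e$end == "dist") e$seg$L else 0,
                   numeric(1))
  sgn <- vapply(ends, function(e) if (e$end == "dist") 1 else -1, numeric(1))
  K <- vapply(seq_len(m), function(i) {
    s <- ends[[i]]$seg
    sqrt(segment_beta(s, node_x[i]) / (2 * rho * segment_Ad(s, node_x[i])))
  }, numeric(1))
  W <- vapply(seq_len(m), function(i) {
    e <- ends[[i]]
    c_ <- K[i] * e$A^0.25
    if (e$end == "dist") e$U + 4 * c_ else e$U - 4 * c_
  }, numeric(1))
  A <- vapply(ends, function(e) e$A, numeric(1))
  for (it in 1:80) {
    c_ <- K * A^0.25
    U <- ifelse(sgn == 1, W - 4 * c_, W + 4 * c_)
    dU <- -sgn * c_ / A
    P <- vapply(seq_len(m), function(i)
      tube_law_pressure(A[i], node_x[i], ends[[i]]$seg), numeric(1))
    TP <- P + 0.5 * rho * U^2
    dTP <- rho * c_^2 / A + rho * U * dU
    mass <- sum(sgn * A * U)
    r <- c(TP[1] - TP[-1], mass)
    scl <- max(abs(TP), 1)
    if (max(abs(r[-m]) / scl, abs(mass) / max(abs(A * U), 1e-12)) < tol) break
    J <- matrix(0, m, m)
    for (k in 2:m) {
      J[k - 1, 1] <- dTP[1]
      J[k - 1, k] <- -dTP[k]
    }
    J[m, ] <- sgn * (U + A * dU)
    A <- A - solve(J, r)
    A <- pmax(A, 0.05 * vapply(seq_len(m), function(i)
      segment_Ad(ends[[i]]$seg, node_x[i]), numeric(1)))
  }
  c_ <- K * A^0.25
  U <- ifelse(sgn == 1, W - 4 * c_, W + 4 * c_)
  P <- vapply(seq_len(m), function(i)
    tube_law_pressure(A[i], node_x[i], ends[[i]]$seg), numeric(1))
  out <- lapply(seq_len(m), function(i) list(A = A[i], U = U[i], P = P[i]))
  attr(out, "mass_residual") <- sum(sgn * A * U)
  attr(out, "pressure_residual") <-
    max(abs((P + 0.5 * rho * U^2) - (P[1] + 0.5 * rho * U[1]^2)))
  out
}

#' @export
print.circ_sim <- function(x, ...) {
  cat(sprintf("<circ_sim> HR %.3g bpm (T = %.3g s), %d cycle(s), %s\n",
              x$hr, x$T, x$cycles,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$residuals))
    cat(sprintf("  final cycle-to-cycle residual: %.3g\n",
                utils::tail(x$residuals, 1)))
  if (is.finite(x$co))
    cat(sprintf("  CO %.3g L/min, LVEDV %.4g mL\n", x$co, x$lvedv))
  cat(sprintf("  sites: %s\n", paste(names(x$records), collapse = ", ")))
  invisible(x)
}

#' @export
summary.circ_sim <- function(object, ...) {
  recs <- object$records
  df <- data.frame(
    site = names(recs),
    P_mean_mmHg = vapply(recs, function(r) mean(r$P) / MMHG_PA, numeric(1)),
    P_pulse_mmHg = vapply(recs, function(r) diff(range(r$P)) / MMHG_PA,
                          numeric(1)),
    Q_mean_Lmin = vapply(recs, function(r) mean(r$Q) / LMIN_M3S, numeric(1)),
    row.names = NULL)
  structure(list(table = df, co = object$co, lvedv = object$lvedv,
                 hr = object$hr, converged = object$converged,
                 cycles = object$cycles), class = "summary.circ_sim")
}

#' @export
print.summary.circ_sim <- function(x, ...) {
  cat(sprintf("Converged: %s after %d cycles; CO %.3g L/min; LVEDV %.4g mL\n",
              x$converged, x$cycles, x$co, x$lvedv))
  print(x$table, digits = 4)
  invisible(x)
}
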