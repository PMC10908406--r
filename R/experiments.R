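#' Fix cardiac output by adjusting preload (Frank-Starling)
#'
#' Iterates on the preload knob (the pulmonary-venous filling pressure) with
#' a secant method on the CO(preload) map until the converged-cycle cardiac
#' output is within `tol` of `target_co`, mirroring the Frank-Starling
#' adjustment of LV end-diastolic volume used to isolate contractility
#' effects from flow effects.
#'
#' @param net a [network_spec()].
#' @param heart a [heart_params()].
#' @param target_co target cardiac output (L/min).
#' @param tol relative CO tolerance (default 1%).
#' @param config a [solver_config()].
#' @param sites monitored sites passed to [simulate_circulation()].
#' @param max_iter maximum secant iterations.
#' @param pfill_bounds admissible filling-pressure range (mmHg).
#' @return list with `heart` (filling pressure updated), `lvedv` (mL),
#'   `co` (L/min), `pfill` (mmHg), `iterations`, and `sim` (the final
#'   converged `circ_sim`).
#' @export
fix_cardiac_output <- function(net, heart, target_co, tol = 0.01,
                               config = solver_config(), sites = NULL,
                               max_iter = 15L, pfill_bounds = c(1, 45)) {
  if (target_co <= 0) stop("fix_cardiac_output: target_co must be > 0")
  if (target_co < 1.4 || target_co > 7.1)
    warning(sprintf("target CO %.2f L/min outside the studied range [1.4, 7.1]",
                    target_co))
  evaluate <- function(pfill, warm) {
    h <- heart; h$Pfill <- pfill
    simulate_circulation(net, heart = h, config = config, sites = sites,
                         init = warm)
  }
  p1 <- heart$Pfill
  sim1 <- evaluate(p1, NULL)
  f1 <- sim1$co - target_co
  if (abs(f1) / target_co < tol) {
    return(list(heart = heart, lvedv = sim1$lvedv, co = sim1$co,
                pfill = p1, iterations = 0L, sim = sim1))
  }
  ## first secant companion: proportional guess (CO roughly linear in Pfill)
  p2 <- min(max(p1 * target_co / max(sim1$co, 0.2), pfill_bounds[1]),
            pfill_bounds[2])
  if (abs(p2 - p1) < 1e-3) p2 <- p1 + if (f1 < 0) 1 else -1
  sim2 <- evaluate(p2, sim1)
  f2 <- sim2$co - target_co
  it <- 1L
  while (abs(f2) / target_co >= tol) {
    if (it >= max_iter)
      stop(sprintf(paste0("fix_cardiac_output: no convergence after %d ",
                          "iterations; last bracket Pfill = (%.3f, %.3f) mmHg, ",
                          "CO = (%.3f, %.3f) L/min, target %.3f"),
                   it, p1, p2, f1 + target_co, f2 + target_co, target_co))
    if (abs(f2 - f1) < 1e-12)
      stop("fix_cardiac_output: flat CO(preload) map, cannot iterate")
    p3 <- p2 - f2 * (p2 - p1) / (f2 - f1)
    p3 <- min(max(p3, pfill_bounds[1]), pfill_bounds[2])
    if (abs(p3 - p2) < 1e-6 && abs(f2) / target_co >= tol)
      stop(sprintf(paste0("fix_cardiac_output: preload pinned at %.2f mmHg ",
                          "with CO %.3f L/min (target %.3f unreachable)"),
                   p3, f2 + target_co, target_co))
    p1 <- p2; f1 <- f2
    sim2 <- evaluate(p3, sim2)
    p2 <- p3; f2 <- sim2$co - target_co
    it <- it + 1L
  }
  heart$Pfill <- p2
  list(heart = heart, lvedv = sim2$lvedv, co = sim2$co, pfill = p2,
       iterations = it, sim = sim2)
}

#' Fix left-ventricular end-diastolic volume by adjusting preload
#'
#' Secant iteration on the filling pressure until the converged-cycle LVEDV
#' matches `target_lvedv`.  Used by the fixed-LVEDV experiment designs,
#' where the preload must not drift with afterload (e.g. when aortic
#' stiffness is varied at "fixed LVEDV").
#'
#' @inheritParams fix_cardiac_output
#' @param target_lvedv target end-diastolic volume (mL).
#' @param tol relative LVEDV tolerance.
#' @return list with `heart`, `lvedv`, `co`, `pfill`, `iterations`, `sim`
#'   (as [fix_cardiac_output()]).
#' @export
fix_lvedv <- function(net, heart, target_lvedv, tol = 0.002,
                      config = solver_config(), sites = NULL,
                      max_iter = 15L, pfill_bounds = c(1, 45)) {
  if (target_lvedv <= 0) stop("fix_lvedv: target_lvedv must be > 0")
  evaluate <- function(pfill, warm) {
    h <- heart; h$Pfill <- pfill
    simulate_circulation(net, heart = h, config = config, sites = sites,
                         init = warm)
  }
  p1 <- heart$Pfill
  sim1 <- evaluate(p1, NULL)
  f1 <- sim1$lvedv - target_lvedv
  if (abs(f1) / target_lvedv < tol)
    return(list(heart = heart, lvedv = sim1$lvedv, co = sim1$co,
                pfill = p1, iterations = 0L, sim = sim1))
  p2 <- min(max(p1 * target_lvedv / sim1$lvedv, pfill_bounds[1]),
            pfill_bounds[2])
  if (abs(p2 - p1) < 1e-3) p2 <- p1 + if (f1 < 0) 0.5 else -0.5
  sim2 <- evaluate(p2, sim1)
  f2 <- sim2$lvedv - target_lvedv
  it <- 1L
  while (abs(f2) / target_lvedv >= tol) {
    if (it >= max_iter || abs(f2 - f1) < 1e-12)
      stop(sprintf("fix_lvedv: no convergence (Pfill %.3f/%.3f, LVEDV %.2f/%.2f, target %.2f)",
                   p1, p2, f1 + target_lvedv, f2 + target_lvedv, target_lvedv))
    p3 <- min(max(p2 - f2 * (p2 - p1) / (f2 - f1), pfill_bounds[1]),
              pfill_bounds[2])
    p1 <- p2; f1 <- f2
    sim2 <- evaluate(p3, sim2)
    p2 <- p3; f2 <- sim2$lvedv - target_lvedv
    it <- it + 1L
  }
  heart$Pfill <- p2
  list(heart = heart, lvedv = sim2$lvedv, co = sim2$co, pfill = p2,
       iterations = it, sim = sim2)
}

#' Define a contractility x heart-rate x stiffness sweep
#'
#' @param ees LV end-systolic elastance values (mmHg/mL); studied range
#'   0.6-5.0, control 2.5.
#' @param hr heart rates (beats/min); studied range 30-180.
#' @param pwv_multiple aortic PWV multiples (>= 1) applied through
#'   [scale_aortic_stiffness()].
#' @param co_mode `"fixed_co"` adjusts preload at every grid point to hold
#'   `target_co`; `"fixed_lvedv"` holds the preload (hence LVEDV) constant
#'   so CO varies with contractility.
#' @param target_co cardiac output target for `"fixed_co"` mode (L/min).
#' @return an object of class `sweep_grid`.
#' @export
sweep_grid <- function(ees = 2.5, hr = 75, pwv_multiple = 1,
                       co_mode = c("fixed_co", "fixed_lvedv"),
                       target_co = 5.6) {
  co_mode <- match.arg(co_mode)
  if (any(ees < 0.6 | ees > 5.0))
    warning("some Ees values are outside the studied range [0.6, 5.0] mmHg/mL")
  if (any(hr < 30 | hr > 180))
    warning("some heart rates are outside the studied range [30, 180] beats/min")
  if (any(pwv_multiple < 1))
    stop("sweep_grid: pwv_multiple must be >= 1")
  structure(list(ees = ees, hr = hr, pwv_multiple = pwv_multiple,
                 co_mode = co_mode, target_co = target_co),
            class = "sweep_grid")
}

#' Run a contractility x heart-rate x stiffness sweep
#'
#' For every grid point: scale the aortic stiffness, set the heart rate and
#' contractility, optionally fix CO via [fix_cardiac_output()], run to the
#' periodic limit cycle and compute the full [hemodynamic_summary()].
#' Deterministic: the model has no stochastic elements, so repeated runs of
#' the same grid give identical tables.  Individual non-convergent points
#' are recorded with `converged = FALSE` and `NA` metrics, not fatal.
#'
#' @param net a [network_spec()] (baseline stiffness).
#' @param heart a [heart_params()] template.
#' @param grid a [sweep_grid()].
#' @param config a [solver_config()].
#' @param carotid,cerebral site names passed to [hemodynamic_summary()].
#' @param verbose print one line per grid point.
#' @return `data.frame` of class `sweep_result`, one row per
#'   (ees, hr, pwv_multiple) with the summary metrics, CO, LVEDV, preload
#'   and convergence metadata.
#' @export
run_sweep <- function(net, heart, grid, config = solver_config(),
                      carotid = "l_carotid",
                      cerebral = c("l_carotid", "r_carotid",
                                   "l_vertebral", "r_vertebral"),
                      verbose = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  rows <- list()
  for (hr in grid$hr) {
    for (ees in grid$ees) {
      lvedv_ref <- NULL   # fixed-LVEDV mode: set by the first stiffness level
      for (m in grid$pwv_multiple) {
        net_m <- scale_aortic_stiffness(net, m)
        h <- set_contractility(set_heart_rate(heart, hr), ees)
        row <- data.frame(ees = ees, hr = hr, pwv_multiple = m,
                          co_mode = grid$co_mode)
        res <- tryCatch({
          if (grid$co_mode == "fixed_co") {
            fx <- fix_cardiac_output(net_m, h, grid$target_co,
                                     config = config)
            sim <- fx$sim
            pfill <- fx$pfill
          } else if (is.null(lvedv_ref)) {
            sim <- simulate_circulation(net_m, heart = h, config = config)
            pfill <- h$Pfill
            lvedv_ref <- sim$lvedv
          } else {
            fx <- fix_lvedv(net_m, h, lvedv_ref, config = config)
            sim <- fx$sim
            pfill <- fx$pfill
          }
          hs <- hemodynamic_summary(sim, net_m, carotid = carotid,
                                    cerebral = cerebral)
          cbind(row, hs,
                data.frame(co = sim$co, lvedv = sim$lvedv, pfill = pfill,
                           cycles = sim$cycles, converged = sim$converged,
                           residual = utils::tail(sim$residuals, 1)))
        }, error = function(e) {
          warning(sprintf("grid point (Ees=%g, HR=%g, m=%g) failed: %s",
                          ees, hr, m, conditionMessage(e)), call. = FALSE)
          cbind(row, data.frame(co = NA_real_, lvedv = NA_real_,
                                pfill = NA_real_, cycles = NA_integer_,
                                converged = FALSE, residual = NA_real_))
        })
        if (verbose)
          message(sprintf("Ees %.2g HR %3g m %.2g: CPP %.3g mW, CO %.3g L/min",
                          ees, hr, m,
                          if ("CPP_mW" %in% names(res)) res$CPP_mW else NA,
                          res$co))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  ## align columns across failed/successful rows
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Heart rate minimising carotid pulsatile power
#'
#' Extracts the CPP(HR) slice at the given contractility and stiffness and
#' returns the grid heart rate with minimal carotid pulsatile power, with
#' the discrete second-difference evidence for an interior minimum
#' (decreasing-then-increasing pattern).
#'
#' @param sweep a `sweep_result` from [run_sweep()].
#' @param ees,pwv_multiple the slice to inspect.
#' @return list with `hr_opt`, `cpp_min` (mW), `interior` (logical: the
#'   minimum is flanked by larger values on both sides), `boundary`
#'   (`TRUE` when the slice is monotone so only a boundary minimum exists)
#'   and the slice itself.
#' @export
find_optimal_hr <- function(sweep, ees, pwv_multiple) {
  sl <- sweep[sweep$ees == ees & sweep$pwv_multiple == pwv_multiple &
                !is.na(sweep$CPP_mW), , drop = FALSE]
  if (nrow(sl) < 3L)
    stop("find_optimal_hr: need at least 3 converged heart rates in the slice")
  sl <- sl[order(sl$hr), ]
  cpp <- sl$CPP_mW
  i <- which.min(cpp)
  interior <- i > 1L && i < nrow(sl)
  list(hr_opt = sl$hr[i], cpp_min = cpp[i], interior = interior,
       boundary = !interior, slice = sl[, c("hr", "CPP_mW", "CPI", "co")])
}

#' Percent change of a metric against a reference row
#'
#' \eqn{100 (x - x_{ref}) / x_{ref}}; the conventional reference is the
#' baseline-stiffness (PWV multiple 1) row of the same (Ees, HR) slice.
#'
#' @param x metric value(s).
#' @param reference reference value.
#' @return percent change.
#' @export
percent_change <- function(x, reference) {
  if (any(reference == 0)) stop("percent_change: zero reference, undefined")
  100 * (x - reference) / reference
}
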