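#' Plot pressure and flow waveforms of a converged simulation
#'
#' Base-graphics panel: pressure (mmHg) and flow (mL/s) over one cycle at
#' the selected sites, plus the LV pressure-volume loop when heart traces
#' were recorded.
#'
#' @param x a `circ_sim`.
#' @param sites site names to draw (default: all, up to 4).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.circ_sim <- function(x, sites = NULL, ...) {
  if (is.null(sites)) sites <- utils::head(names(x$records), 4L)
  sites <- intersect(sites, names(x$records))
  if (!length(sites)) stop("plot.circ_sim: no matching sites")
  has_pv <- !is.null(x$heart_trace)
  op <- par(mfrow = c(if (has_pv) 3 else 2, 1),
            mar = c(4, 4.5, 1.5, 1))
  on.exit(par(op))
  cols <- seq_along(sites) + 1L
  recs <- x$records[sites]
  Pr <- range(vapply(recs, function(r) range(r$P), numeric(2))) / MMHG_PA
  plot(NA, xlim = c(0, x$T), ylim = Pr, xlab = "t (s)",
       ylab = "P (mmHg)", main = sprintf("HR %.3g bpm", x$hr))
  for (i in seq_along(recs))
    lines(recs[[i]]$t, recs[[i]]$P / MMHG_PA, col = cols[i])
  legend("topright", legend = sites, col = cols, lty = 1, bty = "n",
         cex = 0.8)
  Qr <- range(vapply(recs, function(r) range(r$Q), numeric(2))) / ML_M3
  plot(NA, xlim = c(0, x$T), ylim = Qr, xlab = "t (s)", ylab = "Q (mL/s)")
  for (i in seq_along(recs))
    lines(recs[[i]]$t, recs[[i]]$Q / ML_M3, col = cols[i])
  if (has_pv) {
    ht <- x$heart_trace
    plot(ht$V_LV, ht$P_LV, type = "l", xlab = "LV volume (mL)",
         ylab = "LV pressure (mmHg)")
  }
  invisible(x)
}

#' Plot a sweep slice
#'
#' Carotid pulsatile power against heart rate, one line per aortic PWV
#' multiple, at a fixed contractility.
#'
#' @param x a `sweep_result` from [run_sweep()].
#' @param ees contractility slice to draw (default: first value present).
#' @param metric column to draw (default `"CPP_mW"`).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, ees = NULL, metric = "CPP_mW", ...) {
  if (is.null(ees)) ees <- x$ees[1]
  sl <- x[x$ees == ees & !is.na(x[[metric]]), , drop = FALSE]
  if (!nrow(sl)) stop("plot.sweep_result: empty slice")
  ms <- sort(unique(sl$pwv_multiple))
  cols <- seq_along(ms) + 1L
  plot(NA, xlim = range(sl$hr), ylim = range(sl[[metric]]),
       xlab = "heart rate (beats/min)", ylab = metric,
       main = sprintf("Ees = %g mmHg/mL", ees))
  for (i in seq_along(ms)) {
    s2 <- sl[sl$pwv_multiple == ms[i], ]
    s2 <- s2[order(s2$hr), ]
    lines(s2$hr, s2[[metric]], type = "b", col = cols[i], pch = 16)
  }
  legend("topright", legend = sprintf("PWV x%g", ms), col = cols,
         lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
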