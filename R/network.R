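#' Blood properties for the 1-D model
#'
#' Constant Newtonian blood properties together with the velocity-profile
#' constant of the assumed axisymmetric profile.  The wall friction term in
#' the momentum balance is \eqn{2(\xi+2)\pi\mu U/(\rho A)}; the default
#' \eqn{\xi = 9} corresponds to a flat-core profile and yields the
#' \eqn{22\pi\mu U/(\rho A)} friction widely used for large arteries.
#'
#' @param rho blood density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @param xi dimensionless velocity-profile constant (9 = flat core,
#'   2 = Poiseuille).
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1050, mu = 4e-3, xi = 9) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("fluid_properties: rho must be a positive scalar")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("fluid_properties: mu must be a positive scalar")
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0)
    stop("fluid_properties: xi must be a positive scalar")
  structure(list(rho = rho, mu = mu, xi = xi), class = "fluid_properties")
}

#' Construct a 1-D vessel segment
#'
#' A vessel segment is characterised by its length, a linearly tapered
#' diastolic cross-sectional area \eqn{A_d(x)} and a linearly tapered wall
#' coefficient \eqn{\beta(x) = \frac{4}{3}\sqrt{\pi}\,E(x)h(x)} entering the
#' elastic tube law
#' \deqn{P(A, x) = P_{ext} + \frac{\beta(x)}{A_d(x)}(\sqrt{A} - \sqrt{A_d(x)}).}
#' Position `x` is measured from the proximal end; node 0 is the proximal
#' face and nodes are uniformly spaced.
#'
#' Either (`beta_prox`, `beta_dist`) or (`E`, `h`) must be given; in the
#' latter case beta is derived from the elastic modulus and wall thickness.
#'
#' @param id unique segment label (character).
#' @param name anatomical name.
#' @param L segment length (m).
#' @param d_prox,d_dist proximal/distal diastolic internal diameters (m).
#' @param beta_prox,beta_dist wall coefficient at the two ends (Pa m).
#' @param E elastic (Young's) modulus (Pa), scalar or length-2 (prox, dist).
#' @param h wall thickness (m), scalar or length-2.
#' @param Pext external/reference pressure (Pa); the pressure at which the
#'   cross-section equals its diastolic area.
#' @param n_nodes number of spatial nodes (>= 3).
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, name = id, L, d_prox, d_dist = d_prox,
                           beta_prox = NULL, beta_dist = NULL,
                           E = NULL, h = NULL,
                           Pext = 0, n_nodes = 9L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("vessel_segment: id must be a non-empty string")
  if (!is.numeric(L) || L <= 0)
    stop(sprintf("vessel_segment '%s': length L must be > 0", id))
  if (d_prox <= 0 || d_dist <= 0)
    stop(sprintf("vessel_segment '%s': diameters must be > 0", id))
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L)
    stop(sprintf("vessel_segment '%s': n_nodes must be >= 3", id))
  if (is.null(beta_prox)) {
    if (is.null(E) || is.null(h))
      stop(sprintf("vessel_segment '%s': give beta_prox/beta_dist or E and h", id))
    E2 <- rep_len(E, 2L); h2 <- rep_len(h, 2L)
    beta_prox <- (4 / 3) * sqrt(pi) * E2[1L] * h2[1L]
    beta_dist <- (4 / 3) * sqrt(pi) * E2[2L] * h2[2L]
  }
  if (is.null(beta_dist)) beta_dist <- beta_prox
  if (beta_prox <= 0 || beta_dist <= 0)
    stop(sprintf("vessel_segment '%s': beta must be > 0 everywhere", id))
  structure(list(
    id = id, name = name, L = L,
    Ad_prox = pi * d_prox^2 / 4, Ad_dist = pi * d_dist^2 / 4,
    beta_prox = beta_prox, beta_dist = beta_dist,
    Pext = Pext, n_nodes = n_nodes
  ), class = "vessel_segment")
}

## linear taper helpers: s in [0, 1] is x/L
.seg_frac <- function(seg, x) {
  s <- x / seg$L
  if (any(s < -1e-12 | s > 1 + 1e-12))
    stop(sprintf("position x outside segment '%s' [0, %g]", seg$id, seg$L))
  pmin(pmax(s, 0), 1)
}

#' Diastolic area and wall coefficient at a position
#'
#' Linear taper between proximal and distal values.
#'
#' @param seg a [vessel_segment()].
#' @param x position(s) from the proximal end (m).
#' @return numeric vector.
#' @export
segment_Ad <- function(seg, x) {
  s <- .seg_frac(seg, x)
  seg$Ad_prox + s * (seg$Ad_dist - seg$Ad_prox)
}

#' @rdname segment_Ad
#' @export
segment_beta <- function(seg, x) {
  s <- .seg_frac(seg, x)
  seg$beta_prox + s * (seg$beta_dist - seg$beta_prox)
}

#' Node coordinates of a segment
#' @param seg a [vessel_segment()].
#' @return numeric vector of `n_nodes` positions from 0 to `L`.
#' @export
segment_x <- function(seg) seq(0, seg$L, length.out = seg$n_nodes)

#' Elastic tube-law pressure
#'
#' Evaluates \eqn{P = P_{ext} + (\beta(x)/A_d(x))(\sqrt{A} - \sqrt{A_d(x)})},
#' the algebraic pressure-area relation closing the 1-D equations.  Strictly
#' increasing in `A`.
#'
#' @param A cross-sectional area (m^2), vector allowed.
#' @param x position from the proximal end (m); recycled against `A`.
#' @param seg a [vessel_segment()].
#' @return pressure (Pa).
#' @export
tube_law_pressure <- function(A, x, seg) {
  if (any(A <= 0)) stop("tube_law_pressure: A must be > 0")
  Ad <- segment_Ad(seg, x)
  beta <- segment_beta(seg, x)
  seg$Pext + (beta / Ad) * (sqrt(A) - sqrt(Ad))
}

#' Local pulse wave speed
#'
#' From the tube law, \eqn{c^2 = (A/\rho)\,\partial P/\partial A} gives
#' \deqn{c(A, x) = \sqrt{\beta(x)\sqrt{A} / (2 \rho A_d(x))},}
#' which at the diastolic area reduces to
#' \eqn{c_0 = \sqrt{\beta / (2\rho\sqrt{A_d})}}.
#'
#' @inheritParams tube_law_pressure
#' @param fluid a [fluid_properties()].
#' @return wave speed (m/s).
#' @export
wave_speed <- function(A, x, seg, fluid) {
  if (any(A <= 0)) stop("wave_speed: A must be > 0")
  Ad <- segment_Ad(seg, x)
  beta <- segment_beta(seg, x)
  sqrt(beta * sqrt(A) / (2 * fluid$rho * Ad))
}

#' Wall coefficient for a target diastolic wave speed
#'
#' Inverts \eqn{c_0 = \sqrt{\beta/(2\rho\sqrt{A_d})}} to give the beta that
#' produces a prescribed diastolic pulse wave velocity at area `Ad`:
#' \eqn{\beta = 2 \rho \sqrt{A_d}\, c_0^2}.
#'
#' @param c0 target diastolic wave speed (m/s).
#' @param Ad diastolic area (m^2).
#' @param rho blood density (kg/m^3).
#' @return beta (Pa m).
#' @export
beta_for_wave_speed <- function(c0, Ad, rho = 1050) 2 * rho * sqrt(Ad) * c0^2

#' Junction between vessel segments
#'
#' Junctions couple two or more segment ends (series connections,
#' bifurcations, trifurcations) by continuity of total pressure
#' \eqn{P + \rho U^2/2} and conservation of mass, with flows oriented into
#' the junction summing to zero.
#'
#' @param parents list of ends feeding the junction; each end is
#'   `list(segment = <id>, end = "prox"|"dist")`.
#' @param daughters list of ends fed by the junction (same form).
#' @return an object of class `vessel_junction`.
#' @export
junction <- function(parents, daughters) {
  norm_end <- function(e) {
    if (!is.list(e) || is.null(e$segment) || is.null(e$end))
      stop("junction: each end must be list(segment=, end=)")
    if (!e$end %in% c("prox", "dist"))
      stop("junction: end must be 'prox' or 'dist'")
    list(segment = as.character(e$segment), end = e$end)
  }
  if (!is.null(names(parents)) || (length(parents) && !is.list(parents[[1L]])))
    parents <- list(parents)
  if (!is.null(names(daughters)) || (length(daughters) && !is.list(daughters[[1L]])))
    daughters <- list(daughters)
  p <- lapply(parents, norm_end)
  d <- lapply(daughters, norm_end)
  if (length(p) + length(d) < 2L)
    stop("junction: needs at least two attached ends")
  structure(list(parents = p, daughters = d), class = "vessel_junction")
}

#' Terminal attachment of a segment end
#'
#' A terminal couples a free segment end to a three-element Windkessel
#' vascular bed, to the heart (aortic root), or closes it (zero flow).
#'
#' @param segment segment id.
#' @param end `"prox"` or `"dist"`.
#' @param type `"windkessel"`, `"heart"` or `"closed"`.
#' @param bed a [windkessel_bed()] when `type = "windkessel"`.
#' @return an object of class `vessel_terminal`.
#' @export
terminal <- function(segment, end, type = c("windkessel", "heart", "closed"),
                     bed = NULL) {
  type <- match.arg(type)
  if (!end %in% c("prox", "dist")) stop("terminal: end must be 'prox' or 'dist'")
  if (type == "windkessel" && is.null(bed))
    stop(sprintf("terminal at '%s': windkessel terminal needs a bed", segment))
  structure(list(segment = as.character(segment), end = end,
                 type = type, bed = bed), class = "vessel_terminal")
}

#' Assemble and validate a vessel network
#'
#' Checks the connectivity invariants: every segment end attaches to exactly
#' one junction or terminal, all referenced ids exist, and the aortic subset
#' (segments whose wall stiffness is rescaled by [scale_aortic_stiffness()])
#' is a subset of the segment ids.
#'
#' @param segments list of [vessel_segment()]s.
#' @param junctions list of [junction()]s.
#' @param terminals list of [terminal()]s.
#' @param aortic_ids character vector of segment ids designated "aortic".
#' @param fluid a [fluid_properties()].
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(segments, junctions = list(), terminals = list(),
                         aortic_ids = character(), fluid = fluid_properties()) {
  ids <- vapply(segments, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("network_spec: duplicated segment id '%s'",
                 ids[duplicated(ids)][1L]))
  names(segments) <- ids
  ## each end must be used exactly once
  usage <- new.env(parent = emptyenv())
  key <- function(id, end) paste0(id, ":", end)
  use_end <- function(id, end, what) {
    if (!id %in% ids)
      stop(sprintf("network_spec: %s references missing segment '%s'", what, id))
    k <- key(id, end)
    if (!is.null(usage[[k]]))
      stop(sprintf("network_spec: segment end %s attached more than once", k))
    usage[[k]] <- what
  }
  for (j in seq_along(junctions)) {
    jn <- junctions[[j]]
    for (e in c(jn$parents, jn$daughters))
      use_end(e$segment, e$end, sprintf("junction %d", j))
  }
  for (tm in terminals) use_end(tm$segment, tm$end, "terminal")
  dangling <- character()
  for (id in ids) for (end in c("prox", "dist"))
    if (is.null(usage[[key(id, end)]])) dangling <- c(dangling, key(id, end))
  if (length(dangling))
    stop(sprintf("network_spec: dangling segment end(s): %s",
                 paste(dangling, collapse = ", ")))
  if (!all(aortic_ids %in% ids))
    stop(sprintf("network_spec: aortic_ids not among segments: %s",
                 paste(setdiff(aortic_ids, ids), collapse = ", ")))
  structure(list(segments = segments, junctions = junctions,
                 terminals = terminals, aortic_ids = aortic_ids,
                 fluid = fluid), class = "network_spec")
}

#' Rescale aortic stiffness by a pulse-wave-velocity multiple
#'
#' Multiplies the wall coefficient beta of every segment in the network's
#' aortic subset by `m^2`, so that the diastolic pulse wave velocity of
#' those segments scales by `m` (since \eqn{c_0 \propto \sqrt{\beta}}).
#' Non-aortic segments are untouched.  Applying `m1` then `m2` equals
#' applying `m1 * m2`.
#'
#' @param net a [network_spec()].
#' @param m PWV multiple (>= 1); `m = 1` returns the network unchanged.
#' @return the rescaled `network_spec`.
#' @export
scale_aortic_stiffness <- function(net, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("scale_aortic_stiffness: m must be a scalar >= 1")
  for (id in net$aortic_ids) {
    net$segments[[id]]$beta_prox <- net$segments[[id]]$beta_prox * m^2
    net$segments[[id]]$beta_dist <- net$segments[[id]]$beta_dist * m^2
  }
  net
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d segment(s), %d junction(s), %d terminal(s)\n",
              length(x$segments), length(x$junctions), length(x$terminals)))
  cat(sprintf("  aortic subset: %s\n",
              if (length(x$aortic_ids)) paste(x$aortic_ids, collapse = ", ")
              else "(none)"))
  beds <- sum(vapply(x$terminals, function(t) t$type == "windkessel", logical(1)))
  cat(sprintf("  windkessel beds: %d; fluid rho=%g mu=%g xi=%g\n",
              beds, x$fluid$rho, x$fluid$mu, x$fluid$xi))
  invisible(x)
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> '%s' (%s): L=%.3g m, d=%.2f->%.2f mm, c0=%.2f->%.2f m/s (rho 1050)\n",
              x$id, x$name, x$L,
              2000 * sqrt(x$Ad_prox / pi), 2000 * sqrt(x$Ad_dist / pi),
              sqrt(x$beta_prox / (2 * 1050 * sqrt(x$Ad_prox))),
              sqrt(x$beta_dist / (2 * 1050 * sqrt(x$Ad_dist)))))
  invisible(x)
}
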