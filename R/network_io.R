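#' Read and write vessel network files
#'
#' The network file is a single human-editable YAML document so that a full
#' arterial/venous parameterisation can be dropped in as one file.  Schema:
#'
#' ```yaml
#' fluid: {rho: 1050, mu: 0.004, xi: 9}
#' segments:
#'   - id: asc_aorta
#'     name: ascending aorta
#'     length_m: 0.055
#'     d_prox_mm: 28        # diastolic internal diameters
#'     d_dist_mm: 26
#'     E_Pa: 4.0e+05        # either E_Pa + h_mm ... (note the signed
#'                          # exponent: "4.0e5" is a string in YAML)
#'     h_mm: 1.5
#'     # beta_prox_Pa_m: …  # ... or the wall coefficient directly
#'     # beta_dist_Pa_m: …
#'     Pext_Pa: 10665.76    # reference (diastolic) pressure
#'     n_nodes: 9
#'     aortic: yes          # member of the stiffness-scaling subset
#' junctions:
#'   - parents:   [{segment: asc_aorta, end: dist}]
#'     daughters: [{segment: arch_a, end: prox}, {segment: brachioceph, end: prox}]
#' terminals:
#'   - {segment: asc_aorta, end: prox, type: heart}
#'   - segment: r_carotid
#'     end: dist
#'     type: windkessel
#'     bed: {R1: 2.0e+08, C: 6.0e-10, R2: 2.3e+09, P_out: 666.61}
#' ```
#'
#' Resistances are Pa s/m^3, compliances m^3/Pa, pressures Pa.  The writer
#' additionally emits exact diastolic areas (`Ad_prox_m2`, `Ad_dist_m2`) and
#' wall coefficients so that a written file reloads bit-exactly; the reader
#' prefers those exact fields when present and otherwise derives them from
#' the millimetre/modulus fields.
#'
#' @param path file path.
#' @return `load_network` returns a validated [network_spec()];
#'   `save_network` returns `path` invisibly.
#' @name network_io
NULL

#' @rdname network_io
#' @export
load_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$segments) || !length(doc$segments))
    stop("load_network: file has no 'segments' block")
  fl <- doc$fluid
  fluid <- if (is.null(fl)) fluid_properties() else
    fluid_properties(rho = as.numeric(fl$rho %||% 1050),
                     mu = as.numeric(fl$mu %||% 4e-3),
                     xi = as.numeric(fl$xi %||% 9))
  segs <- lapply(doc$segments, .segment_from_yaml)
  aortic <- vapply(doc$segments, function(s) isTRUE(s$aortic), logical(1))
  aortic_ids <- vapply(segs, function(s) s$id, character(1))[aortic]
  juncs <- lapply(doc$junctions %||% list(), function(j) {
    junction(parents = lapply(j$parents %||% list(), identity),
             daughters = lapply(j$daughters %||% list(), identity))
  })
  terms <- lapply(doc$terminals %||% list(), function(tm) {
    type <- tm$type %||% "windkessel"
    bed <- NULL
    if (type == "windkessel") {
      b <- tm$bed
      if (is.null(b))
        stop(sprintf("load_network: windkessel terminal at '%s' lacks a 'bed' block",
                     tm$segment))
      bed <- windkessel_bed(R1 = b$R1, C = b$C, R2 = b$R2,
                            P_out = b$P_out %||% 0,
                            Pc = b$Pc %||% (b$P_out %||% 0))
    }
    terminal(tm$segment, tm$end, type = type, bed = bed)
  })
  network_spec(segs, juncs, terms, aortic_ids = aortic_ids, fluid = fluid)
}

.segment_from_yaml <- function(s) {
  if (is.null(s$id)) stop("load_network: segment without 'id'")
  for (f in c("length_m"))
    if (is.null(s[[f]]))
      stop(sprintf("load_network: segment '%s' lacks '%s'", s$id, f))
  has_beta <- !is.null(s$beta_prox_Pa_m)
  if (!has_beta && (is.null(s$E_Pa) || is.null(s$h_mm)))
    stop(sprintf("load_network: segment '%s' needs E_Pa+h_mm or beta_*_Pa_m", s$id))
  if (is.null(s$d_prox_mm) && is.null(s$Ad_prox_m2))
    stop(sprintf("load_network: segment '%s' needs d_prox_mm or Ad_prox_m2", s$id))
  d_prox <- (s$d_prox_mm %||% 1) / 1000
  d_dist <- (s$d_dist_mm %||% s$d_prox_mm %||% 1) / 1000
  seg <- vessel_segment(
    id = s$id, name = s$name %||% s$id, L = s$length_m,
    d_prox = d_prox, d_dist = d_dist,
    beta_prox = s$beta_prox_Pa_m,
    beta_dist = s$beta_dist_Pa_m %||% s$beta_prox_Pa_m,
    E = if (!has_beta) unlist(s$E_Pa) else NULL,
    h = if (!has_beta) unlist(s$h_mm) / 1000 else NULL,
    Pext = s$Pext_Pa %||% 0,
    n_nodes = s$n_nodes %||% 9L)
  ## exact areas override the rounded mm fields
  if (!is.null(s$Ad_prox_m2)) seg$Ad_prox <- s$Ad_prox_m2
  if (!is.null(s$Ad_dist_m2)) seg$Ad_dist <- s$Ad_dist_m2
  if (seg$Ad_prox <= 0 || seg$Ad_dist <= 0)
    stop(sprintf("load_network: segment '%s' has nonpositive area", s$id))
  seg
}

## %.17g preserves doubles exactly across write/parse; YAML requires a
## signed exponent ("1e+05"), which %g already emits
.yml_num <- function(x) {
  s <- sprintf("%.17g", x)
  ## guarantee the scalar parses as a float/int, never a string
  s
}

#' @rdname network_io
#' @param net a [network_spec()].
#' @export
save_network <- function(net, path) {
  ## the writer emits YAML directly so that every double is printed with
  ## %.17g (exact round trip) and the layout is deterministic
  num <- .yml_num
  ln <- c(sprintf("fluid: {rho: %s, mu: %s, xi: %s}",
                  num(net$fluid$rho), num(net$fluid$mu), num(net$fluid$xi)),
          "segments:")
  for (s in net$segments) {
    ln <- c(ln,
      sprintf("- id: %s", s$id),
      sprintf("  name: %s", s$name),
      sprintf("  length_m: %s", num(s$L)),
      sprintf("  d_prox_mm: %s", num(2000 * sqrt(s$Ad_prox / pi))),
      sprintf("  d_dist_mm: %s", num(2000 * sqrt(s$Ad_dist / pi))),
      sprintf("  Ad_prox_m2: %s", num(s$Ad_prox)),
      sprintf("  Ad_dist_m2: %s", num(s$Ad_dist)),
      sprintf("  beta_prox_Pa_m: %s", num(s$beta_prox)),
      sprintf("  beta_dist_Pa_m: %s", num(s$beta_dist)),
      sprintf("  Pext_Pa: %s", num(s$Pext)),
      sprintf("  n_nodes: %d", s$n_nodes),
      sprintf("  aortic: %s", if (s$id %in% net$aortic_ids) "yes" else "no"))
  }
  endlist <- function(ends) paste0(
    "[", paste(vapply(ends, function(e)
      sprintf("{segment: %s, end: %s}", e$segment, e$end), character(1)),
      collapse = ", "), "]")
  ln <- c(ln, if (length(net$junctions)) "junctions:" else "junctions: []")
  for (j in net$junctions)
    ln <- c(ln, sprintf("- parents: %s", endlist(j$parents)),
            sprintf("  daughters: %s", endlist(j$daughters)))
  ln <- c(ln, if (length(net$terminals)) "terminals:" else "terminals: []")
  for (tm in net$terminals) {
    ln <- c(ln, sprintf("- segment: %s", tm$segment),
            sprintf("  end: %s", tm$end),
            sprintf("  type: %s", tm$type))
    if (tm$type == "windkessel")
      ln <- c(ln, sprintf("  bed: {R1: %s, C: %s, R2: %s, P_out: %s, Pc: %s}",
                          num(tm$bed$R1), num(tm$bed$C), num(tm$bed$R2),
                          num(tm$bed$P_out), num(tm$bed$Pc)))
  }
  writeLines(ln, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
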