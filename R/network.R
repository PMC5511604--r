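#' Vessel segment
#'
#' One compliant tube: linear taper between inlet and outlet radii, uniform
#' or radius-dependent wall thickness, thin-wall elastic law, and an optional
#' embedded fusiform aneurysm.
#'
#' @param name Segment name (unique within a network).
#' @param L Length (m).
#' @param a1,a2 Inlet and outlet lumen radii (m); the healthy radius tapers
#'   linearly between them.
#' @param h Wall thickness (m), or the string "adan" to use the empirical
#'   radius-thickness law of [adan_wall_thickness()] (evaluated on the
#'   healthy radius).
#' @param E Young modulus (Pa).
#' @param poisson Poisson ratio.
#' @param p_ext External (reference) pressure (Pa).
#' @param aneurysm Optional aneurysm description: a list with `kind`
#'   ("arc" or "cosine"), `x1` (bump start, m), `L_A` (bump length, m), and
#'   `D` + `R_s` (m, arc kind) or `k_delta` (cosine kind).
#' @return Object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, L, a1, a2 = a1, h, E, poisson = 0.5,
                           p_ext = 0, aneurysm = NULL) {
  stopifnot(is.character(name), L > 0, a1 > 0, a2 > 0,
            E > 0, poisson >= 0, poisson < 1)
  if (!identical(h, "adan")) stopifnot(is.numeric(h), all(h > 0))
  if (!is.null(aneurysm)) {
    stopifnot(aneurysm$kind %in% c("arc", "cosine"),
              aneurysm$x1 >= 0, aneurysm$L_A > 0,
              aneurysm$x1 + aneurysm$L_A <= L + 1e-12)
    if (aneurysm$kind == "arc" && abs(a1 - a2) > 1e-12)
      stop("vessel_segment: arc aneurysm requires a uniform host radius")
  }
  structure(list(name = name, L = L, a1 = a1, a2 = a2, h = h, E = E,
                 poisson = poisson, p_ext = p_ext, aneurysm = aneurysm),
            class = "vessel_segment")
}

#' Healthy lumen radius of a segment
#' @param seg A [vessel_segment()].
#' @return Function a0(x) on [0, L] (m).
#' @export
seg_healthy_radius <- function(seg) {
  a1 <- seg$a1; a2 <- seg$a2; L <- seg$L
  function(x) a1 + (a2 - a1) * x / L
}

#' Actual lumen radius of a segment (aneurysm included)
#' @param seg A [vessel_segment()].
#' @return Function a(x) on [0, L] (m).
#' @export
seg_radius <- function(seg) {
  a0 <- seg_healthy_radius(seg)
  an <- seg$aneurysm
  if (is.null(an)) return(a0)
  if (an$kind == "arc") {
    prof <- arc_aneurysm_radius(seg$a1, an$D, an$L_A, an$R_s)
    x1 <- an$x1
    function(x) {
      inside <- x >= x1 & x <= x1 + an$L_A
      out <- a0(x)
      out[inside] <- prof(x[inside] - x1)
      out
    }
  } else {
    cosine_aneurysm_radius(a0, an$k_delta, an$x1, an$L_A)
  }
}

#' Wall thickness of a segment
#' @param seg A [vessel_segment()].
#' @return Function h(x) on [0, L] (m); evaluated on the healthy radius for
#'   the "adan" law.
#' @export
seg_thickness <- function(seg) {
  if (identical(seg$h, "adan")) {
    a0 <- seg_healthy_radius(seg)
    function(x) adan_wall_thickness(a0(x) * 100) / 100
  } else {
    hval <- seg$h
    function(x) rep_len(hval, length(x))
  }
}

#' Compliance summary of a segment's aneurysm
#'
#' Computes (K, Delta C_A, tau0, tau) for the aneurysm embedded in a segment,
#' using the segment's own wall law and the local healthy wave speed at the
#' bump midpoint (or a supplied c0).
#'
#' @param seg A [vessel_segment()] with an `aneurysm`.
#' @param fluid A [fluid_properties()].
#' @param c0 Optional wave speed override (m s^-1); default is the healthy
#'   mean speed over the bump footprint.
#' @return A `compliance_summary`.
#' @export
seg_aneurysm_summary <- function(seg, fluid, c0 = NULL) {
  an <- seg$aneurysm
  if (is.null(an)) stop("seg_aneurysm_summary: segment has no aneurysm")
  a0 <- seg_healthy_radius(seg)
  aA <- seg_radius(seg)
  hf <- seg_thickness(seg)
  Ep <- plate_modulus(seg$E, seg$poisson)
  xs <- seq(an$x1, an$x1 + an$L_A, length.out = 101)
  if (is.null(c0))
    c0 <- mean(wave_speed(a0(xs), hf(xs), seg$E, seg$poisson, fluid$density))
  aA_loc <- function(x) aA(x + an$x1)
  a0_loc <- function(x) a0(x + an$x1)
  h_loc <- function(x) hf(x + an$x1)
  attr(aA_loc, "breaks") <- attr(aA, "breaks") - an$x1
  K <- compute_K(aA_loc, a0_loc, an$L_A)
  dCA <- excess_compliance(aA_loc, a0_loc, Ep, h_loc, L_A = an$L_A)
  tau0 <- (an$L_A / 2) / c0
  structure(list(dCA = dCA, K = K, tau0 = tau0, tau = tau0 * K,
                 L_A = an$L_A, c0 = c0),
            class = "compliance_summary")
}

#' Terminal boundary condition
#'
#' @param kind "nonreflecting" or "windkessel" (three-element RCR).
#' @param R1 Proximal resistance (Pa s m^-3); for a reflection-free
#'   termination use the characteristic impedance rho c0 / A0.
#' @param R2 Distal resistance (Pa s m^-3); may be Inf.
#' @param C Compliance (m^3 Pa^-1); 0 gives a purely resistive R1+R2 load.
#' @param p_out Outflow (venous) pressure (Pa).
#' @return Object of class `terminal_bc`.
#' @export
terminal_bc <- function(kind = c("nonreflecting", "windkessel"),
                        R1 = 0, R2 = 0, C = 0, p_out = 0) {
  kind <- match.arg(kind)
  stopifnot(R1 >= 0, R2 >= 0, C >= 0)
  structure(list(kind = kind, R1 = R1, R2 = R2, C = C, p_out = p_out),
            class = "terminal_bc")
}

#' Inlet boundary condition
#'
#' @param series A [waveform()] (velocity, flow or pressure) or a function
#'   of time returning the prescribed value (SI units).
#' @param quantity "velocity", "flow" or "pressure".  Pressure is converted
#'   to the inlet forward characteristic through the linearized impedance
#'   rho c0; flow is imposed exactly through a scalar Newton solve.
#' @param periodic Repeat the series with its own duration as period?
#' @return Object of class `inlet_bc`.
#' @export
inlet_bc <- function(series, quantity = c("velocity", "flow", "pressure"),
                     periodic = FALSE) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(series, "waveform") || is.function(series))
  structure(list(series = series, quantity = quantity, periodic = periodic),
            class = "inlet_bc")
}

#' Assemble a vessel network
#'
#' @param segments List of [vessel_segment()]s (names must be unique).
#' @param junctions List of junctions; each junction is a character vector of
#'   segment ends like `c("main:R", "branch:L", "distal:L")` (2- or 3-way).
#' @param inlet List `list(segment =, end = "L", bc = inlet_bc(...))`.
#' @param terminals List of `list(segment =, end = "R", bc = terminal_bc())`.
#' @param fluid A [fluid_properties()].
#' @param monitors List of `list(segment =, s =)` with fractional position
#'   s in [0, 1].
#' @return Object of class `vessel_network` (validated; see
#'   [validate_network()]).
#' @export
vessel_network <- function(segments, junctions = list(), inlet, terminals,
                           fluid, monitors = list()) {
  names(segments) <- vapply(segments, `[[`, "", "name")
  net <- structure(list(segments = segments, junctions = junctions,
                        inlet = inlet, terminals = terminals,
                        fluid = fluid, monitors = monitors),
                   class = "vessel_network")
  errs <- validate_network(net)
  if (length(errs)) stop("invalid network:\n  - ", paste(errs, collapse = "\n  - "))
  net
}

#' Validate a network description
#'
#' Checks all structural invariants (unique names, every segment end attached
#' to exactly one of inlet/junction/terminal, junction references resolve,
#' positive geometry) and returns the full list of problems rather than
#' stopping at the first.
#'
#' @param net A `vessel_network` (or an un-validated list shaped like one).
#' @return Character vector of error messages; empty when valid.
#' @export
validate_network <- function(net) {
  errs <- character()
  segs <- net$segments
  nm <- vapply(segs, `[[`, "", "name")
  if (anyDuplicated(nm)) errs <- c(errs, "duplicate segment names")
  for (s in segs) {
    if (!(s$a1 > 0) || !(s$a2 > 0))
      errs <- c(errs, sprintf("segment '%s': non-positive radius", s$name))
    if (!(s$L > 0))
      errs <- c(errs, sprintf("segment '%s': non-positive length", s$name))
  }
  parse_end <- function(ref) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !(parts[2] %in% c("L", "R"))) return(NULL)
    parts
  }
  attach_count <- new.env()
  mark <- function(seg, end, what) {
    key <- paste0(seg, ":", end)
    cur <- if (is.null(attach_count[[key]])) character() else attach_count[[key]]
    attach_count[[key]] <- c(cur, what)
  }
  for (j in seq_along(net$junctions)) {
    ends <- net$junctions[[j]]
    if (length(ends) < 2L || length(ends) > 3L)
      errs <- c(errs, sprintf("junction %d: must join 2 or 3 ends", j))
    for (ref in ends) {
      pe <- parse_end(ref)
      if (is.null(pe)) {
        errs <- c(errs, sprintf("junction %d: malformed end '%s'", j, ref))
      } else if (!(pe[1] %in% nm)) {
        errs <- c(errs, sprintf("junction %d: unknown segment '%s'", j, pe[1]))
      } else mark(pe[1], pe[2], sprintf("junction %d", j))
    }
  }
  if (!is.null(net$inlet)) {
    if (!(net$inlet$segment %in% nm))
      errs <- c(errs, sprintf("inlet: unknown segment '%s'", net$inlet$segment))
    else mark(net$inlet$segment, net$inlet$end, "inlet")
  } else errs <- c(errs, "no inlet defined")
  for (tm in net$terminals) {
    if (!(tm$segment %in% nm))
      errs <- c(errs, sprintf("terminal: unknown segment '%s'", tm$segment))
    else mark(tm$segment, tm$end, "terminal")
  }
  for (s in nm) for (e in c("L", "R")) {
    key <- paste0(s, ":", e)
    k <- if (is.null(attach_count[[key]])) 0L else length(attach_count[[key]])
    if (k == 0L)
      errs <- c(errs, sprintf("segment end %s unattached", key))
    if (k > 1L)
      errs <- c(errs, sprintf("segment end %s attached %d times (%s)", key, k,
                              paste(attach_count[[key]], collapse = ", ")))
  }
  for (m in net$monitors) {
    if (!(m$segment %in% nm))
      errs <- c(errs, sprintf("monitor: unknown segment '%s'", m$segment))
    if (m$s < 0 || m$s > 1)
      errs <- c(errs, sprintf("monitor on '%s': s outside [0, 1]", m$segment))
  }
  errs
}

#' Read a network description from JSON
#'
#' Human-scale units at the boundary (cm, mm, kPa), converted to SI once at
#' parse time.  Windkessel parameters are given in SI (Pa s m^-3, m^3 Pa^-1).
#'
#' @param path JSON file with fields `segments`, `junctions`, `inlet`,
#'   `terminals`, `monitors`, `fluid`.
#' @param series A [waveform()] or function for the inlet when the JSON
#'   names no `series_file`.
#' @return A `vessel_network`.
#' @export
network_from_json <- function(path, series = NULL) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  segs <- lapply(cfg$segments, function(s) {
    an <- NULL
    if (!is.null(s$aneurysm)) {
      a <- s$aneurysm
      an <- if (a$kind == "arc")
        list(kind = "arc", x1 = a$x1_cm / 100, L_A = a$L_A_cm / 100,
             D = a$D_mm / 1000, R_s = a$R_s_mm / 1000)
      else
        list(kind = "cosine", x1 = a$x1_cm / 100, L_A = a$L_A_cm / 100,
             k_delta = a$k_delta)
    }
    h <- if (identical(s$h_mm, "adan_law")) "adan" else s$h_mm / 1000
    vessel_segment(s$name, L = s$length_cm / 100,
                   a1 = s$d1_mm / 2000, a2 = s$d2_mm / 2000,
                   h = h, E = s$E_kPa * 1000,
                   poisson = if (is.null(s$poisson)) 0.5 else s$poisson,
                   aneurysm = an)
  })
  if (is.null(series) && !is.null(cfg$inlet$series_file))
    series <- read_waveform(file.path(dirname(path), cfg$inlet$series_file))
  inlet <- list(segment = cfg$inlet$segment,
                end = if (is.null(cfg$inlet$end)) "L" else cfg$inlet$end,
                bc = inlet_bc(series, cfg$inlet$quantity,
                              periodic = isTRUE(cfg$inlet$periodic)))
  terms <- lapply(cfg$terminals, function(tm) {
    list(segment = tm$segment, end = if (is.null(tm$end)) "R" else tm$end,
         bc = terminal_bc(tm$kind,
                          R1 = if (is.null(tm$R1)) 0 else tm$R1,
                          R2 = if (is.null(tm$R2)) 0 else tm$R2,
                          C = if (is.null(tm$C)) 0 else tm$C))
  })
  mons <- lapply(cfg$monitors, function(m) list(segment = m$segment, s = m$s))
  fluid <- fluid_properties(cfg$fluid$density, cfg$fluid$viscosity)
  jn <- cfg$junctions   # uniform 2-way junction lists simplify to a matrix
  if (is.matrix(jn)) jn <- lapply(seq_len(nrow(jn)), function(i) jn[i, ])
  vessel_network(segs, junctions = jn, inlet = inlet,
                 terminals = terms, fluid = fluid, monitors = mons)
}

#' Write a network description to JSON
#'
#' Inverse of [network_from_json()] (the inlet series itself is written
#' separately with [write_waveform()]).
#'
#' @param net A `vessel_network`.
#' @param path Output path.
#' @param series_file Relative path recorded for the inlet series.
#' @return `path`, invisibly.
#' @export
network_to_json <- function(net, path, series_file = NULL) {
  segs <- lapply(net$segments, function(s) {
    out <- list(name = s$name, length_cm = s$L * 100,
                d1_mm = s$a1 * 2000, d2_mm = s$a2 * 2000,
                h_mm = if (identical(s$h, "adan")) "adan_law" else s$h * 1000,
                E_kPa = s$E / 1000, poisson = s$poisson)
    if (!is.null(s$aneurysm)) {
      a <- s$aneurysm
      out$aneurysm <- if (a$kind == "arc")
        list(kind = "arc", x1_cm = a$x1 * 100, L_A_cm = a$L_A * 100,
             D_mm = a$D * 1000, R_s_mm = a$R_s * 1000)
      else
        list(kind = "cosine", x1_cm = a$x1 * 100, L_A_cm = a$L_A * 100,
             k_delta = a$k_delta)
    }
    out
  })
  terms <- lapply(net$terminals, function(tm)
    list(segment = tm$segment, end = tm$end, kind = tm$bc$kind,
         R1 = tm$bc$R1, R2 = tm$bc$R2, C = tm$bc$C))
  cfg <- list(segments = unname(segs), junctions = net$junctions,
              inlet = list(segment = net$inlet$segment, end = net$inlet$end,
                           quantity = net$inlet$bc$quantity,
                           periodic = net$inlet$bc$periodic,
                           series_file = series_file),
              terminals = terms,
              monitors = net$monitors,
              fluid = list(density = net$fluid$density,
                           viscosity = net$fluid$viscosity))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
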