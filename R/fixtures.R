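#' Pump-like inlet velocity pulse
#'
#' Compactly supported velocity pulse emulating a single piston stroke:
#' either a half-sine or a two-humped sum of raised-cosine bumps (the load
#' on a crank-driven piston makes the measured stroke two-humped).  The
#' pulse is scaled so the injected volume through a tube of area `tube_area`
#' matches `stroke_volume`.
#'
#' @param dt Sampling interval (s).
#' @param duration Total pulse duration (s).
#' @param shape "two-hump" or "half-sine".
#' @param tube_area Lumen area at the injection site (m^2).
#' @param stroke_volume Injected volume (m^3); default 100 cm^3.
#' @param hump_centres,hump_widths,hump_amps Two-hump shape parameters
#'   (s, s, relative amplitudes).
#' @param t_lead Quiet lead-in before the pulse (s), for baseline windows.
#' @param t_tail Quiet tail after the pulse (s).
#' @return Velocity [waveform()].
#' @export
pump_pulse <- function(dt = 1e-3, duration = 0.6,
                       shape = c("two-hump", "half-sine"),
                       tube_area, stroke_volume = 100e-6,
                       hump_centres = c(0.075, 0.40),
                       hump_widths = c(0.09, 0.32),
                       hump_amps = c(1, 0.55),
                       t_lead = 0.05, t_tail = 0.2) {
  shape <- match.arg(shape)
  stopifnot(dt > 0, duration > 0, tube_area > 0, stroke_volume >= 0)
  base <- function(t) {
    if (shape == "half-sine") {
      ifelse(t >= 0 & t <= duration, sin(pi * t / duration), 0)
    } else {
      v <- 0
      for (k in seq_along(hump_centres)) {
        z <- (t - hump_centres[k]) / hump_widths[k]
        v <- v + hump_amps[k] *
          ifelse(abs(z) <= 0.5, 0.5 * (1 + cos(2 * pi * z)), 0)
      }
      v
    }
  }
  # closed-form time integral of the unscaled shape
  int0 <- if (shape == "half-sine") 2 * duration / pi
          else sum(hump_amps * hump_widths) / 2
  scale <- if (stroke_volume > 0) stroke_volume / (tube_area * int0) else 0
  t <- seq(0, t_lead + duration + t_tail, by = dt)
  waveform(scale * base(t - t_lead), dt = dt, t_start = 0,
           quantity = "velocity", site = "inlet",
           pulse_start = t_lead)
}

#' Build the laboratory-rig network
#'
#' Compliant latex main tube (ID 17 mm, wall 2 mm, E = 2.8 MPa, 2 m long,
#' 50 cm proximal to the aneurysm segment), a 14 cm aneurysm segment with a
#' centred 9 cm circular-arc bump, approximately rigid inlet tube and outlet
#' fitting (ID 12 mm, stiffened wall), a 6.5 m outlet tube and a wide-tube
#' reservoir with a non-reflecting end.  Working fluid is water.  Pressure
#' and velocity are monitored 2, 10, 25 and 50 cm from the main-tube inlet.
#'
#' @param D Peak aneurysm diameter in mm (24, 34, 44 or 50), or NULL /
#'   "control" for the uniform control tube.
#' @param stroke_volume Pump stroke volume (m^3).
#' @param pulse_shape Inlet pulse shape, see [pump_pulse()].
#' @param dt_series Sampling of the generated inlet series (s).
#' @param stiffness_factor Multiplier on E for the rigid fittings.
#' @return A `fixture_entry`: list with `name`, `network`, and
#'   `ground_truth` (geometry-derived tau, Delta t from the 2 cm site, K,
#'   Delta C_A, c0, x_A; NULL ground truth for the control).
#' @export
build_rig <- function(D = NULL, stroke_volume = 100e-6,
                      pulse_shape = "two-hump", dt_series = 1e-3,
                      stiffness_factor = 100) {
  if (identical(D, "control")) D <- NULL
  if (!is.null(D) && !(D %in% c(24, 34, 44, 50)))
    stop("build_rig: D must be one of 24, 34, 44, 50 mm (or NULL for control)")
  E <- 2.8e6; h <- 2e-3; a_main <- 8.5e-3; a_fit <- 6e-3; sig <- 0.5
  an <- if (!is.null(D))
    list(kind = "arc", x1 = 0.025, L_A = 0.09, D = D * 1e-3, R_s = 0.01)
  segs <- list(
    vessel_segment("inlet-rigid", 0.40, a_fit, a_fit, h, E * stiffness_factor, sig),
    vessel_segment("main-proximal", 0.50, a_main, a_main, h, E, sig),
    vessel_segment("aneurysm-seg", 0.14, a_main, a_main, h, E, sig,
                   aneurysm = an),
    vessel_segment("main-distal", 1.36, a_main, a_main, h, E, sig),
    vessel_segment("fitting-out", 0.06, a_fit, a_fit, h, E * stiffness_factor, sig),
    vessel_segment("outlet-tube", 6.5, a_main, a_main, h, E, sig),
    vessel_segment("reservoir", 0.5, a_main * sqrt(10), a_main * sqrt(10),
                   h, E, sig))
  juncs <- list(c("inlet-rigid:R", "main-proximal:L"),
                c("main-proximal:R", "aneurysm-seg:L"),
                c("aneurysm-seg:R", "main-distal:L"),
                c("main-distal:R", "fitting-out:L"),
                c("fitting-out:R", "outlet-tube:L"),
                c("outlet-tube:R", "reservoir:L"))
  fluid <- fluid_properties(1000, 1e-3)
  series <- pump_pulse(dt = dt_series, tube_area = pi * a_fit^2,
                       stroke_volume = stroke_volume, shape = pulse_shape)
  inlet <- list(segment = "inlet-rigid", end = "L",
                bc = inlet_bc(series, "velocity"))
  terms <- list(list(segment = "reservoir", end = "R",
                     bc = terminal_bc("nonreflecting")))
  mons <- lapply(c(0.02, 0.10, 0.25, 0.50) / 0.50,
                 function(s) list(segment = "main-proximal", s = s))
  net <- vessel_network(segs, juncs, inlet, terms, fluid, mons)
  gt <- NULL
  if (!is.null(D)) {
    c0 <- wave_speed(a_main, h, E, sig, fluid$density)
    summ <- seg_aneurysm_summary(net$segments[["aneurysm-seg"]], fluid, c0 = c0)
    x_A <- (0.50 - 0.02) + 0.025 + 0.045   # 2 cm site -> bump midpoint
    gt <- list(K = summ$K, dCA = summ$dCA, tau = summ$tau, tau0 = summ$tau0,
               c0 = c0, x_A = x_A, dt_lag = 2 * x_A / c0, L_A = 0.09)
  }
  structure(list(name = if (is.null(D)) "rig-control" else sprintf("rig-D%d", D),
                 network = net, ground_truth = gt),
            class = "fixture_entry")
}

# monitored aortic/carotid segments: number, short name, L (cm), D1, D2 (mm)
.chain_table <- function() {
  data.frame(
    number = c("1", "3", "15", "19a", "19b", "27", "29", "31", "33a", "33b",
               "35", "41", "43", "45", "47", "5", "14"),
    name = c("arch1", "arch2", "arch3", "arch4", "thor1", "thor2", "thor3",
             "thor4", "thor5", "thor6", "abd1", "abd2", "abd3", "abd4",
             "abd5", "rcc", "lcc"),
    L_cm = c(7.44, 0.96, 0.70, 4.31, 0.99, 0.79, 1.56, 0.53, 12.16, 0.32,
             1.40, 0.43, 1.20, 10.60, 1.00, 8.12, 12.13),
    D1_mm = c(31.9, 25.9, 25.1, 24.6, 21.1, 20.7, 20.4, 19.8, 19.6, 15.1,
              15.0, 14.6, 14.5, 14.2, 12.9, 9.0, 9.0),
    D2_mm = c(25.9, 25.1, 24.6, 21.1, 20.7, 20.4, 19.8, 19.6, 15.1, 15.0,
              14.6, 14.5, 14.2, 12.9, 11.8, 6.7, 6.7),
    stringsAsFactors = FALSE)
}

#' Build the reduced aortic-chain network
#'
#' Serial chain of the fifteen aortic segments monitored in the reference
#' arterial tree (aortic arch to abdominal aorta V) with two carotid-like
#' side branches at the arch, empirical radius-dependent wall thickness,
#' E = 225 kPa, incompressible walls, and blood properties (rho = 1040
#' kg m^-3, mu = 4 mPa s).  Omitted side branches are absorbed into
#' three-element Windkessel terminals with characteristic-impedance-matched
#' proximal resistance.  A fusiform cosine-bump aneurysm can be embedded in
#' the abdominal aorta IV segment: peak radius 2x (AAA-2) or 3x (AAA-3) the
#' healthy radius.
#'
#' @param aaa "none", "AAA2" or "AAA3".
#' @param period Heartbeat period (s).
#' @param stroke_volume Inlet stroke volume per beat (m^3).
#' @param systole Ejection duration (s).
#' @param total_resistance Net peripheral resistance (Pa s m^-3) distributed
#'   over the three outlets.
#' @param wk_decay Windkessel pressure-decay time R2 C (s).
#' @return A `fixture_entry` with `name`, `network`, `ground_truth`
#'   (aneurysm tau, K, Delta C_A, and per-site round-trip reference lags
#'   `dt_ref`), and `table` (the segment table used).
#' @export
build_aorta_chain <- function(aaa = c("none", "AAA2", "AAA3"), period = 1,
                              stroke_volume = 85e-6, systole = 0.3,
                              total_resistance = 1.7e8, wk_decay = 1.3) {
  aaa <- match.arg(aaa)
  tab <- .chain_table()
  fluid <- fluid_properties(1040, 4e-3)
  E <- 225e3; sig <- 0.5
  k_delta <- switch(aaa, none = NULL, AAA2 = 1, AAA3 = 2)
  # the printed rest geometry is referenced at mean arterial pressure, so
  # the working point of the tube law sits at p_ext (keeps c near the
  # printed averaged wave speeds during the run)
  p_ref <- stroke_volume / period * total_resistance
  segs <- lapply(seq_len(nrow(tab)), function(i) {
    an <- NULL
    if (tab$name[i] == "abd4" && !is.null(k_delta))
      an <- list(kind = "cosine", x1 = 0.001, L_A = 0.104, k_delta = k_delta)
    vessel_segment(tab$name[i], L = tab$L_cm[i] / 100,
                   a1 = tab$D1_mm[i] / 2000, a2 = tab$D2_mm[i] / 2000,
                   h = "adan", E = E, poisson = sig, p_ext = p_ref,
                   aneurysm = an)
  })
  names(segs) <- tab$name
  aorta <- tab$name[1:15]
  juncs <- list(c("arch1:R", "arch2:L", "rcc:L"),
                c("arch2:R", "arch3:L", "lcc:L"))
  for (i in 3:14)
    juncs <- c(juncs, list(c(paste0(aorta[i], ":R"), paste0(aorta[i + 1], ":L"))))
  # inlet: periodic systolic ejection, imposed as a flow rate
  Q0 <- 2 * stroke_volume / systole             # peak of sin^2 ejection
  q_fun <- local({
    Tp <- period; Ts <- systole; Q0 <- Q0
    function(t) {
      tt <- t %% Tp
      ifelse(tt < Ts, Q0 * sin(pi * tt / Ts)^2, 0)
    }
  })
  inlet <- list(segment = "arch1", end = "L", bc = inlet_bc(q_fun, "flow"))
  # Windkessel terminals: matched R1, weighted distal resistance
  wk_for <- function(seg_name, weight) {
    s <- segs[[seg_name]]
    a2 <- s$a2
    h2 <- seg_thickness(s)(s$L)
    c2 <- wave_speed(a2, h2, s$E, s$poisson, fluid$density)
    A2 <- pi * a2^2
    R1 <- fluid$density * c2 / A2
    Rtot <- total_resistance / weight
    R2 <- max(Rtot - R1, 0.1 * Rtot)
    terminal_bc("windkessel", R1 = R1, R2 = R2, C = wk_decay / R2)
  }
  terms <- list(list(segment = "abd5", end = "R", bc = wk_for("abd5", 0.7)),
                list(segment = "rcc", end = "R", bc = wk_for("rcc", 0.15)),
                list(segment = "lcc", end = "R", bc = wk_for("lcc", 0.15)))
  mons <- lapply(tab$name, function(nm) list(segment = nm, s = 0.5))
  net <- vessel_network(segs, juncs, inlet, terms, fluid, mons)

  # per-segment average wave speed from the healthy geometry
  c0_avg <- vapply(segs, function(s) {
    xs <- seq(0, s$L, length.out = 41)
    mean(wave_speed(seg_healthy_radius(s)(xs), seg_thickness(s)(xs),
                    s$E, s$poisson, fluid$density))
  }, 0)
  gt <- list(c0_avg = c0_avg)
  if (!is.null(k_delta)) {
    s45 <- net$segments[["abd4"]]
    summ <- seg_aneurysm_summary(s45, fluid, c0 = c0_avg[["abd4"]])
    # round-trip reference lag from the centre of each monitored segment
    # (carotids: from their inlet junction) to the aneurysm-bump centre
    pos_an <- 0.001 + 0.104 / 2     # within abd4
    i45 <- match("abd4", aorta)
    dt_ref <- numeric(nrow(tab)); names(dt_ref) <- tab$name
    for (i in seq_len(nrow(tab))) {
      nm <- tab$name[i]
      if (nm %in% aorta) {
        j <- match(nm, aorta)
        Ls <- tab$L_cm[1:15] / 100
        tt <- (Ls[j] / 2) / c0_avg[j]                     # centre -> own outlet
        if (j < i45) {
          k <- seq(j + 1, i45 - 1)
          if (length(k)) tt <- tt + sum(Ls[k] / c0_avg[k])
          tt <- tt + pos_an / c0_avg[i45]
        } else tt <- NA_real_   # sites distal to the AAA not referenced
        dt_ref[i] <- 2 * tt
      } else {
        # carotid: from the branch-off junction to the bump centre
        entry <- if (nm == "rcc") 1L else 2L              # after arch1 / arch2
        k <- seq(entry + 1, i45 - 1)
        Ls <- tab$L_cm[1:15] / 100
        tt <- sum(Ls[k] / c0_avg[k]) + pos_an / c0_avg[i45]
        dt_ref[i] <- 2 * tt
      }
    }
    gt <- c(gt, list(K = summ$K, dCA = summ$dCA, tau = summ$tau,
                     tau0 = summ$tau0, L_A = 0.104,
                     c0_site = c0_avg[["abd4"]], dt_ref = dt_ref))
  }
  structure(list(name = paste0("aorta-chain-",
                               switch(aaa, none = "healthy", AAA2 = "AAA2",
                                      AAA3 = "AAA3")),
                 network = net, ground_truth = gt, table = tab,
                 period = period,
                 # expected mean arterial pressure: mean inflow x net
                 # peripheral resistance; use as init_pressure for fast
                 # convergence to the periodic state
                 init_pressure = p_ref),
            class = "fixture_entry")
}

#' Fixture catalogue
#'
#' Named constructors for every shipped test network.
#'
#' @param name One of "rig-control", "rig-D24", "rig-D34", "rig-D44",
#'   "rig-D50", "aorta-chain-healthy", "aorta-chain-AAA2",
#'   "aorta-chain-AAA3".
#' @param ... Passed to [build_rig()] or [build_aorta_chain()].
#' @return A `fixture_entry`.
#' @export
fixture <- function(name, ...) {
  switch(name,
         "rig-control" = build_rig(NULL, ...),
         "rig-D24" = build_rig(24, ...),
         "rig-D34" = build_rig(34, ...),
         "rig-D44" = build_rig(44, ...),
         "rig-D50" = build_rig(50, ...),
         "aorta-chain-healthy" = build_aorta_chain("none", ...),
         "aorta-chain-AAA2" = build_aorta_chain("AAA2", ...),
         "aorta-chain-AAA3" = build_aorta_chain("AAA3", ...),
         stop("unknown fixture: ", name))
}

#' Names of all shipped fixtures
#' @return Character vector accepted by [fixture()].
#' @export
fixture_names <- function() {
  c("rig-control", "rig-D24", "rig-D34", "rig-D44", "rig-D50",
    "aorta-chain-healthy", "aorta-chain-AAA2", "aorta-chain-AAA3")
}

#' Add seeded white Gaussian noise to a waveform
#'
#' Noise standard deviation is `rel_sigma` times the RMS of the signal;
#' the global RNG state is saved and restored, so the result is a pure
#' function of (waveform, rel_sigma, seed).
#'
#' @param w A [waveform()].
#' @param rel_sigma Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return Noisy [waveform()].
#' @export
add_noise <- function(w, rel_sigma, seed) {
  stopifnot(inherits(w, "waveform"), rel_sigma >= 0)
  if (rel_sigma == 0) return(w)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rms <- sqrt(mean(w$values^2))
  wf_with(w, w$values + stats::rnorm(length(w), 0, rel_sigma * rms))
}
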