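#' Discretize a network
#'
#' Samples every segment on a uniform per-segment grid at (close to) the
#' requested spacing, including both segment ends, and evaluates the rest
#' geometry (lumen area, tube-law stiffness, wall thickness) at the nodes.
#' Aneurysm bumps are included through [seg_radius()].
#'
#' @param net A `vessel_network`.
#' @param dx Target node spacing (m).  Every segment must satisfy
#'   L >= 2 dx (at least 3 nodes).
#' @return Object of class `pulse_mesh`: per-segment node data.
#' @export
discretize <- function(net, dx = 0.01) {
  stopifnot(dx > 0)
  short <- vapply(net$segments, function(s) s$L < 2 * dx, TRUE)
  if (any(short))
    stop("discretize: dx too coarse for segment(s): ",
         paste(names(net$segments)[short], collapse = ", "),
         " (need L >= 2 dx)")
  segs <- lapply(net$segments, function(s) {
    n <- max(3L, as.integer(round(s$L / dx)) + 1L)
    x <- seq(0, s$L, length.out = n)
    h <- seg_thickness(s)(x)
    a <- seg_radius(s)(x)
    A0 <- pi * a^2
    beta <- sqrt(pi) * h * plate_modulus(s$E, s$poisson) / A0
    list(name = s$name, n = n, dx = s$L / (n - 1L), x = x,
         A0 = A0, beta = beta, h = h, p_ext = s$p_ext,
         sqrtA0 = sqrt(A0),
         beta_h = 0.5 * (beta[-n] + beta[-1L]),
         sqrtA0_h = sqrt(0.5 * (A0[-n] + A0[-1L])),
         c0 = sqrt(beta * sqrt(A0) / (2 * net$fluid$density)))
  })
  structure(list(segments = segs, fluid = net$fluid), class = "pulse_mesh")
}

# local wave speed from area
.wspeed <- function(A, beta, rho) sqrt(beta * sqrt(A) / (2 * rho))

# Characteristic foot-point invariant leaving a segment end (old state).
# On tapered geometry the raw invariants u +/- 4c are not constant at rest,
# so the PERTURBATION invariants u +/- 4 (c - c0(x)) are advected instead:
# they vanish identically at rest for any geometry.
# end = "R": outgoing u + 4(c - c0); end = "L": outgoing u - 4(c - c0)
.outgoing_invariant <- function(A, u, beta, c0, rho, dx, dt, end) {
  n <- length(A)
  if (end == "R") {
    c1 <- .wspeed(A[n], beta[n], rho); c2 <- .wspeed(A[n - 1L], beta[n - 1L], rho)
    f <- (u[n] + c1) * dt / dx
    f <- min(max(f, 0), 1)
    (1 - f) * (u[n] + 4 * (c1 - c0[n])) + f * (u[n - 1L] + 4 * (c2 - c0[n - 1L]))
  } else {
    c1 <- .wspeed(A[1L], beta[1L], rho); c2 <- .wspeed(A[2L], beta[2L], rho)
    f <- (c1 - u[1L]) * dt / dx
    f <- min(max(f, 0), 1)
    (1 - f) * (u[1L] - 4 * (c1 - c0[1L])) + f * (u[2L] - 4 * (c2 - c0[2L]))
  }
}

# Solve one junction: unknown areas at the incident end nodes.
# ends: list of lists(W, dir (+1 right end, -1 left end), beta, A0, p_ext)
# Returns list of (A, u) per end.
.junction_solve <- function(ends, A_init, rho, dyn_pressure = TRUE,
                            tol = 1e-10, max_iter = 50L) {
  m <- length(ends)
  W <- vapply(ends, `[[`, 0, "W")
  dir <- vapply(ends, `[[`, 0, "dir")
  beta <- vapply(ends, `[[`, 0, "beta")
  pext <- vapply(ends, `[[`, 0, "p_ext")
  c0n <- vapply(ends, `[[`, 0, "c0")
  sqrtA0 <- sqrt(vapply(ends, `[[`, 0, "A0"))
  A <- A_init
  scaleQ <- max(abs(A_init) * .wspeed(A_init, beta, rho))
  scaleP <- max(rho * .wspeed(A_init, beta, rho)^2)
  resid <- function(A) {
    c <- .wspeed(A, beta, rho)
    u <- W - dir * 4 * (c - c0n)
    p <- pext + beta * (sqrt(A) - sqrtA0)
    pt <- p + if (dyn_pressure) 0.5 * rho * u^2 else 0
    c(sum(dir * A * u) / scaleQ, (pt[-1L] - pt[1L]) / scaleP)
  }
  g <- resid(A)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol)
      break
    c <- .wspeed(A, beta, rho)
    u <- W - dir * 4 * (c - c0n)
    J <- matrix(0, m, m)
    dQdA <- dir * (u - dir * c)           # d(dir*A*u)/dA
    dptdA <- rho * c^2 / A + if (dyn_pressure) -dir * rho * u * c / A else 0
    J[1L, ] <- dQdA / scaleQ
    if (m > 1L) for (k in 2:m) {
      J[k, k] <- dptdA[k] / scaleP
      J[k, 1L] <- -dptdA[1L] / scaleP
    }
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      A_new <- A + lam * step
      if (all(A_new > 0)) {
        g_new <- resid(A_new)
        if (max(abs(g_new)) < max(abs(g)) || lam < 1e-4) break
      }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    A <- A + lam * step
    g <- resid(A)
  }
  if (max(abs(g)) > 1e-6)
    stop(sprintf("junction_solve: Newton failed (residual %.3g; A = %s)",
                 max(abs(g)), paste(signif(A, 4), collapse = ", ")))
  c_f <- .wspeed(A, beta, rho)
  list(A = A, u = W - dir * 4 * (c_f - c0n))
}

# Three-element Windkessel (RCR) terminal update at a right end.
# Solves the outgoing-characteristic / lumped-model coupling implicitly.
# Returns list(A, u, p1) with the new capacitor-node pressure p1.
.windkessel_solve <- function(W, beta, A0, c0n, p_ext, rho, bc, p1, dt, A_init) {
  sqrtA0 <- sqrt(A0)
  R1 <- bc$R1; R2 <- bc$R2; C <- bc$C; pv <- bc$p_out
  A <- A_init
  for (it in 1:50) {
    c <- .wspeed(A, beta, rho)
    u <- W - 4 * (c - c0n)
    p <- p_ext + beta * (sqrt(A) - sqrtA0)
    Q <- A * u
    dQdA <- u - c
    dpdA <- rho * c^2 / A
    if (C > 0) {
      if (is.finite(R2)) {
        den <- 1 + dt / (C * R2)
        p1n <- (p1 + (dt / C) * (Q + pv / R2)) / den
        dp1dA <- (dt / C) * dQdA / den
      } else {
        p1n <- p1 + (dt / C) * Q
        dp1dA <- (dt / C) * dQdA
      }
      f <- p - R1 * Q - p1n
      df <- dpdA - R1 * dQdA - dp1dA
    } else {
      Rtot <- R1 + if (is.finite(R2)) R2 else 0
      if (!is.finite(R2))
        stop("windkessel_solve: C = 0 with R2 = Inf blocks the outlet")
      f <- p - Rtot * Q - pv
      df <- dpdA - Rtot * dQdA
    }
    if (abs(f) < 1e-10 * max(rho * c^2, 1)) break
    step <- -f / df
    while (A + step <= 0) step <- step / 2
    A <- A + step
  }
  c <- .wspeed(A, beta, rho)
  u <- W - 4 * (c - c0n)
  Q <- A * u
  if (C > 0) {
    p1 <- if (is.finite(R2)) (p1 + (dt / C) * (Q + pv / R2)) / (1 + dt / (C * R2))
          else p1 + (dt / C) * Q
  }
  list(A = A, u = u, p1 = p1)
}

#' Run a pulse-wave simulation
#'
#' Integrates the 1D continuity/momentum system with the pressure-area
#' closure on the whole network using a two-step (Richtmyer) explicit
#' second-order scheme in the (A, u) variables, with characteristic-based
#' inlet, junction and terminal boundary conditions and the Poiseuille
#' friction source.
#'
#' @param net A `vessel_network`.
#' @param duration Simulated time (s).  In periodic mode this is
#'   `cycles * period`.
#' @param dx Target node spacing (m); see [discretize()].
#' @param cfl CFL number (<= 0.9); the time step is
#'   cfl * min(dx / c_max) with a 15\% headroom on the rest wave speed.
#' @param out_dt Output sampling interval of the returned waveforms (s).
#' @param mode "single" (one pulse from rest) or "periodic" (run `cycles`
#'   cycles, return the last one).
#' @param period Cycle period (s), periodic mode.
#' @param cycles Number of cycles, periodic mode.
#' @param dyn_pressure Include the 1/2 rho u^2 term in the junction
#'   total-pressure balance (TRUE, the physical choice).
#' @param init_pressure Uniform initial transmural pressure (Pa).  For
#'   periodic runs, initializing near the expected mean arterial pressure
#'   (mean inflow times net peripheral resistance) removes the slow
#'   Windkessel charging transient so three cycles reach a periodic state.
#' @param speed_margin Headroom factor on the rest wave speed when fixing
#'   the time step; must exceed max (|u| + c) / c0 attained during the run
#'   (blood flow can reach u ~ 0.5 c, hence the generous default).
#' @param dissipation Coefficient of the pressure-sensor (JST-type)
#'   artificial dissipation that stabilizes steep area gradients; 0
#'   disables it.  The sensor is quadratic in the solution curvature, so
#'   smooth waveforms are essentially unaffected.
#' @return Object of class `pulse_sim`: `sites` (per monitored site, a list
#'   of `p`, `u`, `q`, `a` [waveform()]s), `volume` (injected / outflow /
#'   stored, single mode), `cycle_convergence` (max pressure change between
#'   the last two cycles, periodic mode), and solver metadata.
#' @export
run_simulation <- function(net, duration = NULL, dx = 0.01, cfl = 0.5,
                           out_dt = 1e-3, mode = c("single", "periodic"),
                           period = 1, cycles = 3L, dyn_pressure = TRUE,
                           dissipation = 0.75, speed_margin = 1.4,
                           init_pressure = 0) {
  mode <- match.arg(mode)
  stopifnot(cfl > 0, cfl <= 0.9)
  if (mode == "periodic") duration <- cycles * period
  if (is.null(duration)) stop("run_simulation: duration required")
  mesh <- discretize(net, dx)
  rho <- net$fluid$density
  mu <- net$fluid$viscosity
  nseg <- length(mesh$segments)
  seg_names <- vapply(mesh$segments, `[[`, "", "name")

  # initial state: rest at the prescribed transmural pressure
  A_start <- lapply(mesh$segments, function(s)
    (s$sqrtA0 + (init_pressure - s$p_ext) / s$beta)^2)
  # fixed time step from initial-state speeds with headroom for the pulse
  dt <- cfl * min(vapply(seq_along(mesh$segments), function(si) {
    s <- mesh$segments[[si]]
    s$dx / (speed_margin * max(.wspeed(A_start[[si]], s$beta, rho)))
  }, 0))
  nsteps <- ceiling(duration / dt)
  dt <- duration / nsteps

  # resolve attachments ------------------------------------------------
  si_of <- function(name) {
    i <- match(name, seg_names)
    if (is.na(i)) stop("unknown segment: ", name)
    i
  }
  inlet_si <- si_of(net$inlet$segment)
  if (net$inlet$end != "L")
    stop("run_simulation: inlet must attach to a segment's left end")
  terminals <- lapply(net$terminals, function(tm) {
    if (tm$end != "R")
      stop("run_simulation: terminals must attach to right ends")
    # capacitor node starts consistent with the initial pressure field
    p1_0 <- if (tm$bc$kind == "windkessel" && is.finite(tm$bc$R2) &&
                tm$bc$R1 + tm$bc$R2 > 0)
      tm$bc$p_out + (init_pressure - tm$bc$p_out) *
        tm$bc$R2 / (tm$bc$R1 + tm$bc$R2)
    else tm$bc$p_out
    list(si = si_of(tm$segment), bc = tm$bc, p1 = p1_0)
  })
  junctions <- lapply(net$junctions, function(j) {
    lapply(j, function(ref) {
      parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
      list(si = si_of(parts[1]), end = parts[2],
           dir = if (parts[2] == "R") 1 else -1)
    })
  })

  # prescribed inlet values at every step, precomputed ------------------
  bc_in <- net$inlet$bc
  t_new <- (1:nsteps) * dt
  if (is.function(bc_in$series)) {
    inflow <- vapply(t_new, bc_in$series, 0)
  } else {
    w <- bc_in$series
    tw <- wf_time(w)
    tq <- if (bc_in$periodic) ((t_new - w$t_start) %% ((length(w)) * w$dt)) + w$t_start
          else t_new
    if (!bc_in$periodic && max(tq) > max(tw) + 1e-12)
      warning("run_simulation: inlet series shorter than run; holding last value")
    inflow <- stats::approx(tw, w$values, xout = pmin(pmax(tq, tw[1]), max(tw)),
                            rule = 2)$y
  }
  in_seg <- mesh$segments[[inlet_si]]
  if (bc_in$quantity == "pressure")   # linearized impedance conversion
    inflow <- (inflow - in_seg$p_ext) / (rho * in_seg$c0[1])

  # monitors -------------------------------------------------------------
  mons <- lapply(net$monitors, function(m) {
    si <- si_of(m$segment)
    s <- mesh$segments[[si]]
    pos <- m$s * (s$n - 1L)
    i0 <- min(max(floor(pos) + 1L, 1L), s$n - 1L)
    list(si = si, i0 = i0, w = pos - (i0 - 1L),
         label = sprintf("%s@%g", m$segment, m$s))
  })
  nmon <- length(mons)
  rec_p <- matrix(NA_real_, nsteps + 1L, max(nmon, 1L))
  rec_u <- matrix(NA_real_, nsteps + 1L, max(nmon, 1L))
  rec_a <- matrix(NA_real_, nsteps + 1L, max(nmon, 1L))

  # initial state ------------------------------------------------------
  A <- A_start
  u <- lapply(mesh$segments, function(s) numeric(s$n))
  A_init <- A
  vol_in <- 0; vol_out <- 0

  press <- function(si, Avec) {
    s <- mesh$segments[[si]]
    s$p_ext + s$beta * (sqrt(Avec) - s$sqrtA0)
  }
  record <- function(row) {
    for (k in seq_len(nmon)) {
      m <- mons[[k]]; s <- mesh$segments[[m$si]]
      Av <- A[[m$si]]; uv <- u[[m$si]]
      i <- m$i0; w1 <- 1 - m$w
      pv <- s$p_ext + s$beta[i:(i + 1L)] * (sqrt(Av[i:(i + 1L)]) - s$sqrtA0[i:(i + 1L)])
      rec_p[row, k] <<- w1 * pv[1] + m$w * pv[2]
      rec_u[row, k] <<- w1 * uv[i] + m$w * uv[i + 1L]
      rec_a[row, k] <<- w1 * Av[i] + m$w * Av[i + 1L]
    }
  }
  record(1L)

  visc_coef <- 8 * pi * mu / rho
  for (step in seq_len(nsteps)) {
    A_new <- A; u_new <- u
    # interior update (Richtmyer two-step) per segment
    for (si in seq_len(nseg)) {
      s <- mesh$segments[[si]]
      n <- s$n; hdx <- s$dx
      Av <- A[[si]]; uv <- u[[si]]
      p <- s$p_ext + s$beta * (sqrt(Av) - s$sqrtA0)
      F1 <- Av * uv
      F2 <- 0.5 * uv^2 + p / rho
      S2 <- -visc_coef * uv / Av
      i1 <- seq_len(n - 1L)
      r <- dt / (2 * hdx)
      Ah <- 0.5 * (Av[i1] + Av[i1 + 1L]) - r * (F1[i1 + 1L] - F1[i1])
      uh <- 0.5 * (uv[i1] + uv[i1 + 1L]) - r * (F2[i1 + 1L] - F2[i1]) +
        0.25 * dt * (S2[i1] + S2[i1 + 1L])
      if (any(Ah <= 0) || anyNA(Ah))
        stop(sprintf("run_simulation: instability in segment '%s' at t = %.4g s",
                     s$name, step * dt))
      ph <- s$p_ext + s$beta_h * (sqrt(Ah) - s$sqrtA0_h)
      F1h <- Ah * uh
      F2h <- 0.5 * uh^2 + ph / rho
      S2h <- -visc_coef * uh / Ah
      j <- seq.int(2L, n - 1L)
      rr <- dt / hdx
      A_new[[si]][j] <- Av[j] - rr * (F1h[j] - F1h[j - 1L])
      u_new[[si]][j] <- uv[j] - rr * (F2h[j] - F2h[j - 1L]) +
        0.5 * dt * (S2h[j] + S2h[j - 1L])
      if (dissipation > 0 && n >= 4L) {
        # pressure-sensor (JST-type) dissipation: damps only the sawtooth
        # oscillations that steep area gradients excite; inert on smooth waves
        dp <- abs(p[3:n] - 2 * p[2:(n - 1L)] + p[1:(n - 2L)])
        sen <- dp / (abs(p[3:n]) + 2 * abs(p[2:(n - 1L)]) + abs(p[1:(n - 2L)]) +
                       1e-3 * rho * s$c0[2:(n - 1L)]^2)   # s_i, i = 2..n-1
        sh <- pmax(sen[c(1L, seq_len(n - 2L))], sen[c(seq_len(n - 2L), n - 2L)])
        cv <- .wspeed(Av, s$beta, rho)
        lam <- pmax(abs(uv[i1]) + cv[i1], abs(uv[i1 + 1L]) + cv[i1 + 1L])
        nu <- dissipation * sh * lam
        dAp <- Av - s$A0                 # dissipate the perturbation only,
        dA <- nu * (dAp[i1 + 1L] - dAp[i1])   # not the rest-geometry gradient
        du <- nu * (uv[i1 + 1L] - uv[i1])
        A_new[[si]][j] <- A_new[[si]][j] + rr * (dA[j] - dA[j - 1L])
        u_new[[si]][j] <- u_new[[si]][j] + rr * (du[j] - du[j - 1L])
      }
    }
    # inlet: prescribe u (or linearized p), extrapolate backward invariant
    {
      s <- mesh$segments[[inlet_si]]
      Wb <- .outgoing_invariant(A[[inlet_si]], u[[inlet_si]], s$beta, s$c0,
                                rho, s$dx, dt, "L")
      if (bc_in$quantity == "flow") {
        # solve A (u = Wb + 4c(A)) so that A u matches the prescribed flow
        Q_in <- inflow[step]
        A_in <- A[[inlet_si]][1]
        for (it in 1:30) {
          c_in <- .wspeed(A_in, s$beta[1], rho)
          u_in <- Wb + 4 * (c_in - s$c0[1])
          f <- A_in * u_in - Q_in
          if (abs(f) < 1e-14 + 1e-10 * abs(Q_in)) break
          stp <- -f / (u_in + c_in)
          while (A_in + stp <= 0) stp <- stp / 2
          A_in <- A_in + stp
        }
        u_in <- Wb + 4 * (.wspeed(A_in, s$beta[1], rho) - s$c0[1])
      } else {
        u_in <- inflow[step]
        c_in <- s$c0[1] + (u_in - Wb) / 4
        if (c_in <= 0)
          stop("run_simulation: inlet characteristic collapse (c <= 0)")
        A_in <- (2 * rho * c_in^2 / s$beta[1])^2
      }
      A_new[[inlet_si]][1] <- A_in
      u_new[[inlet_si]][1] <- u_in
      vol_in <- vol_in + A_in * u_in * dt
    }
    # junctions
    for (jn in junctions) {
      ends <- lapply(jn, function(e) {
        s <- mesh$segments[[e$si]]
        node <- if (e$end == "R") s$n else 1L
        list(W = .outgoing_invariant(A[[e$si]], u[[e$si]], s$beta, s$c0,
                                     rho, s$dx, dt, e$end),
             dir = e$dir, beta = s$beta[node], A0 = s$A0[node],
             c0 = s$c0[node], p_ext = s$p_ext)
      })
      A_cur <- vapply(seq_along(jn), function(k) {
        e <- jn[[k]]
        A[[e$si]][if (e$end == "R") mesh$segments[[e$si]]$n else 1L]
      }, 0)
      sol <- .junction_solve(ends, A_cur, rho, dyn_pressure)
      for (k in seq_along(jn)) {
        e <- jn[[k]]
        node <- if (e$end == "R") mesh$segments[[e$si]]$n else 1L
        A_new[[e$si]][node] <- sol$A[k]
        u_new[[e$si]][node] <- sol$u[k]
      }
    }
    # terminals
    for (ti in seq_along(terminals)) {
      tm <- terminals[[ti]]
      s <- mesh$segments[[tm$si]]
      n <- s$n
      Wf <- .outgoing_invariant(A[[tm$si]], u[[tm$si]], s$beta, s$c0,
                                rho, s$dx, dt, "R")
      if (tm$bc$kind == "nonreflecting") {
        # incoming perturbation invariant at rest value (zero)
        c_t <- s$c0[n] + Wf / 8
        A_t <- (2 * rho * c_t^2 / s$beta[n])^2
        u_t <- Wf / 2
      } else {
        sol <- .windkessel_solve(Wf, s$beta[n], s$A0[n], s$c0[n], s$p_ext, rho,
                                 tm$bc, tm$p1, dt, A[[tm$si]][n])
        A_t <- sol$A; u_t <- sol$u
        terminals[[ti]]$p1 <- sol$p1
      }
      A_new[[tm$si]][n] <- A_t
      u_new[[tm$si]][n] <- u_t
      vol_out <- vol_out + A_t * u_t * dt
    }
    A <- A_new; u <- u_new
    record(step + 1L)
    if (step %% 50L == 0L) {   # periodic CFL / sanity audit
      for (si in seq_len(nseg)) {
        s <- mesh$segments[[si]]
        cmax <- max(abs(u[[si]]) + .wspeed(A[[si]], s$beta, rho))
        if (cmax * dt / s$dx > 1)
          stop(sprintf("run_simulation: CFL violated in segment '%s' at t = %.4g s",
                       s$name, step * dt))
      }
    }
  }

  stored <- sum(vapply(seq_len(nseg), function(si) {
    s <- mesh$segments[[si]]
    dA <- A[[si]] - A_init[[si]]
    sum((dA[-1L] + dA[-s$n]) / 2) * s$dx
  }, 0))

  # resample records to the uniform output grid -------------------------
  t_sim <- (0:nsteps) * dt
  make_wf <- function(vals, t_out, t_off, quantity, label) {
    v <- stats::approx(t_sim, vals, xout = t_out, rule = 2)$y
    waveform(v, dt = out_dt, t_start = 0, quantity = quantity, site = label)
  }
  if (mode == "periodic") {
    t_out_last <- seq((cycles - 1L) * period, duration, by = out_dt)
    t_out_prev <- t_out_last - period
    conv <- 0
    conv_site <- numeric(nmon)
    sites <- list()
    for (k in seq_len(nmon)) {
      lb <- mons[[k]]$label
      p_last <- stats::approx(t_sim, rec_p[, k], xout = t_out_last, rule = 2)$y
      p_prev <- stats::approx(t_sim, rec_p[, k], xout = t_out_prev, rule = 2)$y
      conv_site[k] <- max(abs(p_last - p_prev))
      conv <- max(conv, conv_site[k])
      sites[[lb]] <- list(
        p = waveform(p_last, out_dt, 0, "pressure", site = lb),
        p_prev = waveform(p_prev, out_dt, 0, "pressure", site = lb),
        u = waveform(stats::approx(t_sim, rec_u[, k], xout = t_out_last, rule = 2)$y,
                     out_dt, 0, "velocity", site = lb),
        a = waveform(stats::approx(t_sim, rec_a[, k], xout = t_out_last, rule = 2)$y,
                     out_dt, 0, "area", site = lb))
      sites[[lb]]$q <- wf_with(sites[[lb]]$a, sites[[lb]]$a$values *
                                 sites[[lb]]$u$values, "flow", "m^3/s")
    }
    names(conv_site) <- vapply(mons, `[[`, "", "label")
    res <- list(sites = sites, cycle_convergence = conv,
                cycle_convergence_site = conv_site)
  } else {
    t_out <- seq(0, duration, by = out_dt)
    sites <- list()
    for (k in seq_len(nmon)) {
      lb <- mons[[k]]$label
      sites[[lb]] <- list(
        p = make_wf(rec_p[, k], t_out, 0, "pressure", lb),
        u = make_wf(rec_u[, k], t_out, 0, "velocity", lb),
        a = make_wf(rec_a[, k], t_out, 0, "area", lb))
      sites[[lb]]$q <- wf_with(sites[[lb]]$a, sites[[lb]]$a$values *
                                 sites[[lb]]$u$values, "flow", "m^3/s")
    }
    res <- list(sites = sites,
                volume = list(injected = vol_in, outflow = vol_out,
                              stored = stored))
  }
  res$dt_solver <- dt
  res$nsteps <- nsteps
  res$mesh <- mesh
  class(res) <- "pulse_sim"
  res
}

#' @export
print.pulse_sim <- function(x, ...) {
  cat(sprintf("<pulse_sim> %d steps, dt = %.3g s, %d monitored site(s)\n",
              x$nsteps, x$dt_solver, length(x$sites)))
  if (!is.null(x$cycle_convergence))
    cat(sprintf("  cycle-to-cycle max |dp| = %.4g Pa\n", x$cycle_convergence))
  if (!is.null(x$volume))
    cat(sprintf("  volume: injected %.4g, out %.4g, stored %.4g m^3\n",
                x$volume$injected, x$volume$outflow, x$volume$stored))
  invisible(x)
}
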