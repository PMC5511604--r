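#' Fluid properties
#'
#' Container for the working-fluid density and dynamic viscosity used by the
#' solver and the wave-analysis routines.
#'
#' @param density Fluid density rho (kg m^-3). Water is 1000, blood about 1040.
#' @param viscosity Dynamic viscosity mu (Pa s). Use 0 for an inviscid run;
#'   blood is about 4e-3.
#' @return An object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties(1040, 4e-3)
#' @export
fluid_properties <- function(density, viscosity = 0) {
  stopifnot(is.numeric(density), length(density) == 1L, density > 0,
            is.numeric(viscosity), length(viscosity) == 1L, viscosity >= 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Effective plate modulus
#'
#' E' = E / (1 - sigma^2), the analogue of the Young modulus for thin plates
#' and shells; enters the tube law and the pulse-wave speed.
#'
#' @param E Young modulus (Pa).
#' @param poisson Poisson ratio sigma, in [0, 0.5] for ordinary materials
#'   (0.5 = incompressible wall).
#' @return Effective modulus (Pa).
#' @export
plate_modulus <- function(E, poisson) {
  stopifnot(all(E > 0), all(poisson >= 0), all(poisson < 1))
  E / (1 - poisson^2)
}

#' Unperturbed pulse-wave speed in a compliant tube
#'
#' Moens-Korteweg-type speed c0 = sqrt(h E' / (2 rho a0)) with
#' E' = E/(1 - sigma^2).  Equivalently c0 = sqrt(beta sqrt(A0) / (2 rho))
#' with the tube-law stiffness beta = sqrt(pi) h E' / A0.
#'
#' @param a0 Lumen radius (m).
#' @param h Wall thickness (m).
#' @param E Young modulus (Pa).
#' @param poisson Poisson ratio.
#' @param rho Fluid density (kg m^-3).
#' @return Wave speed (m s^-1).  Vectorized over all arguments.
#' @examples
#' wave_speed(8.5e-3, 2e-3, 2.8e6, 0.5, 1000)  # ~21 m/s, laboratory latex tube
#' @export
wave_speed <- function(a0, h, E, poisson, rho) {
  if (any(a0 <= 0) || any(h <= 0) || any(E <= 0) || any(rho <= 0))
    stop("wave_speed: all of a0, h, E, rho must be positive")
  if (any(poisson < 0) || any(poisson >= 1))
    stop("wave_speed: poisson ratio must lie in [0, 1)")
  sqrt(h * plate_modulus(E, poisson) / (2 * rho * a0))
}

#' Tube-law stiffness coefficient
#'
#' beta = dp/d(sqrt(A)) at A = A0, i.e. sqrt(pi) h E' / A0.
#'
#' @inheritParams wave_speed
#' @return beta (Pa m^-1).
#' @export
tube_beta <- function(a0, h, E, poisson) {
  A0 <- pi * a0^2
  sqrt(pi) * h * plate_modulus(E, poisson) / A0
}

#' Empirical arterial wall thickness
#'
#' Wall thickness as a function of lumen radius for systemic arteries,
#' h = a0 (0.2802 e^{-5.053 a0} + 0.1324 e^{-0.1114 a0}), with the radius
#' expressed in centimetres (the convention of the source network model).
#'
#' @param a0_cm Lumen radius in centimetres.
#' @return Wall thickness in centimetres.  Vectorized.
#' @examples
#' adan_wall_thickness(1.0)  # 0.1202 cm
#' @export
adan_wall_thickness <- function(a0_cm) {
  if (any(a0_cm <= 0)) stop("adan_wall_thickness: radius must be positive")
  a0_cm * (0.2802 * exp(-5.053 * a0_cm) + 0.1324 * exp(-0.1114 * a0_cm))
}

#' Circular-arc fusiform aneurysm profile
#'
#' Axisymmetric bump used for the laboratory aneurysm phantoms: the
#' generatrix is a central outward circular arc of radius R_A, smoothly
#' (tangentially) conjugated to the straight vessel wall at both ends
#' through arcs of radius R_s.  The free radius R_A is fixed by requiring
#' tangency of the two arcs together with the peak radius D/2 at the bump
#' midpoint; it is found by 1-D root finding.
#'
#' @param a_v Healthy (host-vessel) lumen radius (m).
#' @param D Peak inner diameter of the aneurysm (m); must satisfy D >= 2 a_v.
#' @param L_A Full bump footprint length (m), conjugation arcs included.
#' @param R_s Conjugation-arc radius (m).
#' @return A function a_A(x) giving the lumen radius on [0, L_A] (clamped to
#'   a_v outside), with attributes `breaks` (profile breakpoints useful for
#'   piecewise quadrature), `R_A`, and the construction parameters.
#' @examples
#' prof <- arc_aneurysm_radius(8.5e-3, 50e-3, 90e-3, 10e-3)
#' prof(45e-3)  # 25 mm peak radius
#' @export
arc_aneurysm_radius <- function(a_v, D, L_A, R_s) {
  stopifnot(a_v > 0, D > 0, L_A > 0, R_s > 0)
  if (D < 2 * a_v) stop("arc_aneurysm_radius: peak diameter below host diameter")
  X <- L_A / 2
  if (D == 2 * a_v) {
    f <- function(x) rep_len(a_v, length(x))
    attributes(f) <- list(breaks = c(0, L_A), R_A = Inf,
                          a_v = a_v, D = D, L_A = L_A, R_s = R_s)
    class(f) <- c("arc_aneurysm", "function")
    return(f)
  }
  # Tangency residual for the central-arc radius: external tangency between
  # the conjugation circle centred at (0, a_v + R_s) and the central circle
  # centred at (L_A/2, D/2 - R_A).
  tang <- function(R_A) {
    X^2 + (D / 2 - R_A - a_v - R_s)^2 - (R_A + R_s)^2
  }
  upper <- (X^2 + (D / 2 - a_v)^2) / (D - 2 * a_v) + R_s + D
  if (tang(.Machine$double.eps) * tang(upper) > 0)
    stop("arc_aneurysm_radius: no tangent central arc fits (bump too tall for L_A, R_s)")
  R_A <- stats::uniroot(tang, c(.Machine$double.eps, upper), tol = 1e-14)$root
  # tangency point along the line joining the two centres
  c1 <- c(0, a_v + R_s)
  c2 <- c(X, D / 2 - R_A)
  x_t <- c1[1] + R_s * (c2[1] - c1[1]) / (R_A + R_s)
  # the tangency must sit on the lower branch of the conjugation circle
  # (otherwise the generatrix is not single-valued in x)
  if (!(R_A > 0) || x_t < 0 || x_t > X || x_t > R_s || c2[2] > c1[2])
    stop("arc_aneurysm_radius: geometry infeasible for given (D, L_A, R_s)")
  f <- function(x) {
    xm <- ifelse(x > X, L_A - x, x)           # symmetric about the midpoint
    out <- rep_len(a_v, length(x))
    conj <- xm >= 0 & xm <= x_t
    cent <- xm > x_t & xm <= X
    out[conj] <- a_v + R_s - sqrt(R_s^2 - xm[conj]^2)
    out[cent] <- (D / 2 - R_A) + sqrt(pmax(R_A^2 - (X - xm[cent])^2, 0))
    out
  }
  attributes(f) <- list(breaks = sort(unique(c(0, x_t, X, L_A - x_t, L_A))),
                        R_A = R_A, x_t = x_t,
                        a_v = a_v, D = D, L_A = L_A, R_s = R_s)
  class(f) <- c("arc_aneurysm", "function")
  f
}

#' Cosine-bump aneurysm profile
#'
#' Fusiform bump with a raised-cosine radius increment proportional to the
#' local healthy radius:
#' a(x) = a0(x) + k_delta a0(x) (1 - cos(2 pi (x - x1)/L_A)) / 2 on
#' [x1, x1 + L_A], a0 elsewhere.  k_delta = 1 doubles the radius at the bump
#' midpoint, k_delta = 2 triples it.
#'
#' @param a0 Healthy radius: a function of x (m) or a single number.
#' @param k_delta Non-negative increment scale factor.
#' @param x1 Bump start coordinate (m).
#' @param L_A Bump length (m).
#' @return Function a(x) with attribute `breaks` = c(x1, x1 + L_A).
#' @export
cosine_aneurysm_radius <- function(a0, k_delta, x1, L_A) {
  stopifnot(L_A > 0, k_delta >= 0)
  a0f <- if (is.function(a0)) a0 else function(x) rep_len(a0, length(x))
  f <- function(x) {
    base <- a0f(x)
    s <- (x - x1) / L_A
    bump <- ifelse(s >= 0 & s <= 1, 0.5 * (1 - cos(2 * pi * s)), 0)
    base * (1 + k_delta * bump)
  }
  attributes(f) <- list(breaks = c(x1, x1 + L_A),
                        k_delta = k_delta, x1 = x1, L_A = L_A)
  class(f) <- c("cosine_aneurysm", "function")
  f
}

# integrate g over [lo, hi], splitting at supplied interior breakpoints so the
# adaptive quadrature never straddles a curvature kink
.piecewise_integrate <- function(g, lo, hi, breaks = NULL, rel.tol = 1e-10) {
  pts <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  tot <- 0
  for (i in seq_len(length(pts) - 1L)) {
    tot <- tot + stats::integrate(g, pts[i], pts[i + 1L],
                                  rel.tol = rel.tol, abs.tol = 0,
                                  subdivisions = 400L)$value
  }
  tot
}

#' Dimensionless excess-compliance ratio K
#'
#' K = (1/L_A) * integral over the bump of (a_A(x)^3 / a_v(x)^3 - 1) dx:
#' the ratio of the aneurysm's excess compliance to the compliance of a
#' healthy vessel of the same length (uniform wall stiffness).  For tapered
#' hosts the ratio is taken pointwise.
#'
#' @param a_A Aneurysm lumen-radius function on [0, L_A] (or a profile from
#'   [arc_aneurysm_radius()] / [cosine_aneurysm_radius()]).
#' @param a_v Healthy radius: function on [0, L_A] or a single number.
#' @param L_A Aneurysm length (m).  Defaults to the profile's own footprint
#'   when `a_A` carries one.
#' @return K (dimensionless, >= 0 for outward bumps).
#' @examples
#' compute_K(cosine_aneurysm_radius(1, 1, 0, 1), 1, 1)  # 47/16
#' @export
compute_K <- function(a_A, a_v, L_A = attr(a_A, "L_A")) {
  stopifnot(is.function(a_A), is.numeric(L_A), L_A > 0)
  a_vf <- if (is.function(a_v)) a_v else function(x) rep_len(a_v, length(x))
  probe <- a_vf(seq(0, L_A, length.out = 33))
  if (any(probe <= 0)) stop("compute_K: healthy radius must be positive")
  g <- function(x) (a_A(x) / a_vf(x))^3 - 1
  .piecewise_integrate(g, 0, L_A, attr(a_A, "breaks")) / L_A
}

#' Excess compliance of an aneurysm
#'
#' Delta C_A = integral over the bump of
#' (2 pi a_A^3 / (E'_A h_A) - 2 pi a_v^3 / (E'_v h_v)) dx, the additional
#' volume compliance of the vessel caused by the aneurysm.  With uniform
#' wall stiffness this reduces to (2 pi / (E' h)) * integral (a_A^3 - a_v^3)
#' and, for a constant host radius, to 2 pi a_v^3 L_A K / (E' h).
#'
#' @param a_A,a_v Lumen-radius functions (m) on [0, L_A]; `a_v` may be a
#'   number.
#' @param Eprime_A,Eprime_v Effective wall moduli E' (Pa); functions of x or
#'   numbers.
#' @param h_A,h_v Wall thicknesses (m); functions of x or numbers.
#' @param L_A Aneurysm length (m).
#' @return Excess compliance (m^3 Pa^-1).
#' @export
excess_compliance <- function(a_A, a_v, Eprime_A, h_A,
                              Eprime_v = Eprime_A, h_v = h_A,
                              L_A = attr(a_A, "L_A")) {
  stopifnot(is.function(a_A), L_A > 0)
  fun <- function(v) if (is.function(v)) v else function(x) rep_len(v, length(x))
  a_vf <- fun(a_v); EAf <- fun(Eprime_A); hAf <- fun(h_A)
  Evf <- fun(Eprime_v); hvf <- fun(h_v)
  probe <- seq(0, L_A, length.out = 33)
  if (any(EAf(probe) <= 0) || any(hAf(probe) <= 0) ||
      any(Evf(probe) <= 0) || any(hvf(probe) <= 0))
    stop("excess_compliance: wall stiffness fields must be positive")
  g <- function(x) {
    2 * pi * (a_A(x)^3 / (EAf(x) * hAf(x)) - a_vf(x)^3 / (Evf(x) * hvf(x)))
  }
  .piecewise_integrate(g, 0, L_A, attr(a_A, "breaks"))
}

#' Reflection characteristic time from geometry
#'
#' tau = tau0 * K with tau0 = (L_A/2)/c0, the time for the pulse to traverse
#' half the aneurysm.  tau is the lumped time constant of the aneurysm's
#' reflection kernel.
#'
#' @param L_A Aneurysm length (m).
#' @param c0 Pulse-wave speed of the host vessel (m s^-1).
#' @param K Dimensionless compliance ratio from [compute_K()].
#' @return tau (s).
#' @examples
#' tau_from_geometry(0.104, 4.36, 47 / 16)  # 35.0 ms
#' @export
tau_from_geometry <- function(L_A, c0, K) {
  stopifnot(L_A > 0, c0 > 0, K >= 0)
  (L_A / (2 * c0)) * K
}

#' Compliance summary of an aneurysm profile
#'
#' Bundles the lumped parameters used by the detector: excess compliance
#' Delta C_A, compliance ratio K, half-transit time tau0 and characteristic
#' time tau = tau0 K.
#'
#' @param a_A Aneurysm radius function on [0, L_A].
#' @param a_v Healthy radius (function or number).
#' @param L_A Aneurysm length (m).
#' @param Eprime Effective wall modulus E' (Pa), assumed uniform.
#' @param h Wall thickness (m), assumed uniform.
#' @param c0 Host-vessel pulse-wave speed (m s^-1).
#' @return An object of class `compliance_summary` with fields
#'   `dCA` (m^3 Pa^-1), `K`, `tau0` (s), `tau` (s).
#' @export
compliance_summary <- function(a_A, a_v, L_A, Eprime, h, c0) {
  K <- compute_K(a_A, a_v, L_A)
  dCA <- excess_compliance(a_A, a_v, Eprime, h, L_A = L_A)
  tau0 <- (L_A / 2) / c0
  structure(list(dCA = dCA, K = K, tau0 = tau0, tau = tau0 * K,
                 L_A = L_A, c0 = c0),
            class = "compliance_summary")
}

#' @export
print.compliance_summary <- function(x, ...) {
  cat("Aneurysm compliance summary\n")
  cat(sprintf("  K      = %.4g\n", x$K))
  cat(sprintf("  dC_A   = %.4g m^3/Pa (%.4g cm^3/MPa)\n", x$dCA, x$dCA * 1e12))
  cat(sprintf("  tau0   = %.4g ms\n", x$tau0 * 1e3))
  cat(sprintf("  tau    = %.4g ms\n", x$tau * 1e3))
  invisible(x)
}
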