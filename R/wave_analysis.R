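#' Separate a pressure/velocity pair into forward and backward waves
#'
#' Linear (small-amplitude) separation: p_f = (p + rho c0 u)/2 and
#' p_b = (p - rho c0 u)/2.  The pressure is first referenced to its
#' pre-pulse baseline so that both components start from zero at rest.
#'
#' @param p Pressure [waveform()] (Pa).
#' @param u Velocity [waveform()] (m/s), co-sampled with `p` at the same site.
#' @param rho Fluid density (kg m^-3).
#' @param c0 Local unperturbed pulse-wave speed (m s^-1).
#' @param baseline_window Length (s) of the initial window whose mean defines
#'   the pressure (and velocity) baseline; 0 disables referencing.
#' @return List with `p_f` and `p_b` waveforms (Pa, relative to baseline).
#' @export
separate_waves <- function(p, u, rho, c0, baseline_window = 0.05) {
  stopifnot(inherits(p, "waveform"), inherits(u, "waveform"))
  if (length(p) != length(u) || abs(p$dt - u$dt) > 1e-12 ||
      abs(p$t_start - u$t_start) > 1e-9)
    stop("separate_waves: p and u must be co-sampled (same length, dt, start)")
  pv <- p$values
  uv <- u$values
  if (baseline_window > 0) {
    nb <- max(1L, min(length(pv), round(baseline_window / p$dt)))
    pv <- pv - mean(pv[seq_len(nb)])
    uv <- uv - mean(uv[seq_len(nb)])
  }
  p_f <- wf_with(p, (pv + rho * c0 * uv) / 2)
  p_b <- wf_with(p, (pv - rho * c0 * uv) / 2)
  list(p_f = p_f, p_b = p_b)
}

# discrete normalized Gaussian kernel values for width delta at spacing dt
.gauss_kernel <- function(delta, dt) {
  half <- max(1L, ceiling(3.5 * delta / dt))
  k <- exp(-((-half:half) * dt / delta)^2)
  k / sum(k)
}

#' Gaussian high-pass filter
#'
#' Returns w - G*w where G is a Gaussian of width delta normalized to unit
#' discrete sum; removes components slower than ~1/delta.  A sinusoid at
#' angular frequency omega is scaled by 1 - exp(-omega^2 delta^2 / 4).
#' End effects are handled by reflect-padding over the kernel support.
#'
#' @param w A [waveform()].
#' @param delta Gaussian width (s).  A warning is raised when delta < 2 dt
#'   (under-resolved kernel).
#' @return High-passed [waveform()] with the same metadata.
#' @export
gaussian_highpass <- function(w, delta) {
  stopifnot(inherits(w, "waveform"), delta > 0)
  if (delta < 2 * w$dt)
    warning("gaussian_highpass: delta < 2*dt, kernel under-resolved")
  k <- .gauss_kernel(delta, w$dt)
  half <- (length(k) - 1L) %/% 2L
  v <- w$values
  n <- length(v)
  pad <- min(half, n - 1L)
  ext <- c(v[pad:1 + 1L], v, v[n - seq_len(pad)])   # reflect both ends
  if (pad < half) { # short record relative to kernel: extend with edge values
    ext <- c(rep(ext[1], half - pad), ext, rep(ext[length(ext)], half - pad))
  }
  sm <- stats::filter(ext, k, method = "convolution", sides = 2)
  sm <- as.numeric(sm)[half + seq_len(n)]
  wf_with(w, v - sm)
}

#' Aneurysm reflection coefficient in the frequency domain
#'
#' R(omega) = (i omega tau / (1 - i omega tau)) exp(i omega Delta t): the
#' reflection from a lumped compliant insertion Delta C_A located half a
#' round trip Delta t away.  |R| -> 0 at low frequency and -> 1 at high
#' frequency; |R| = 1/sqrt(2) at omega tau = 1.
#'
#' @param omega Angular frequency (rad s^-1), vectorized.
#' @param tau Characteristic time (s), > 0.
#' @param dt_lag Round-trip lag Delta t (s), >= 0.
#' @return Complex reflection coefficient(s).
#' @export
kernel_freq <- function(omega, tau, dt_lag = 0) {
  stopifnot(tau > 0, dt_lag >= 0)
  (1i * omega * tau / (1 - 1i * omega * tau)) * exp(1i * omega * dt_lag)
}

# Fractional-delay via FFT phase shift (band-limited interpolation).
# Signal is zero-padded well past the shifted support to avoid wrap-around.
.fft_delay <- function(v, dt, shift_s) {
  n <- length(v)
  nsh <- shift_s / dt
  if (abs(nsh - round(nsh)) < 1e-9) {  # integer shift: exact
    k <- round(nsh)
    if (k >= 0) return(c(rep(0, min(k, n)), v)[seq_len(n)])
    return(c(v[(-k + 1L):n], rep(0, min(-k, n))))
  }
  m <- stats::nextn(n + ceiling(abs(nsh)) + 64L, 2)
  vp <- c(v, rep(0, m - n))
  freq <- c(0:(m %/% 2), -(m %/% 2 - 1):-1) / (m * dt)   # Hz
  ph <- exp(-2i * pi * freq * shift_s)
  out <- Re(stats::fft(stats::fft(vp) * ph, inverse = TRUE)) / m
  out[seq_len(n)]
}

#' Predicted backward wave from the reflection kernel
#'
#' Convolves a forward wave with the time-domain kernel
#' R(t) = -delta(t - Dt) + H(t - Dt) (1/tau) exp(-(t - Dt)/tau):
#' p_b(t) = -p_f(t - Dt) + (1/tau) int p_f(t') exp(-(t - Dt - t')/tau) dt'.
#' The delta term is applied as an exact shifted copy; the exponential tail
#' uses the exact one-pole recursion for piecewise-linear input (stable for
#' tau comparable to dt); fractional-sample lags use band-limited (FFT)
#' interpolation.
#'
#' @param p_f Forward [waveform()] starting from rest.
#' @param tau Characteristic time (s) > 0.
#' @param dt_lag Round-trip lag Delta t (s) >= 0.
#' @return Backward-wave [waveform()] on the same sample grid.
#' @export
reflect_convolve <- function(p_f, tau, dt_lag = 0) {
  stopifnot(inherits(p_f, "waveform"), tau > 0, dt_lag >= 0)
  dur <- (length(p_f) - 1L) * p_f$dt
  if (dt_lag > dur) {
    warning("reflect_convolve: lag beyond record, returning zeros")
    return(wf_with(p_f, numeric(length(p_f))))
  }
  g <- .reflect_zero_lag(p_f$values, p_f$dt, tau)
  wf_with(p_f, .fft_delay(g, p_f$dt, dt_lag))
}

# zero-lag response g = -p + (1/tau) int_-inf^t p(t') exp(-(t-t')/tau) dt'
# exact for piecewise-linear p: one-pole exponential-integrator recursion
.reflect_zero_lag <- function(p, dt, tau) {
  n <- length(p)
  th <- dt / tau
  al <- exp(-th)
  c1 <- 1 - (1 - al) / th       # weight of the newer sample
  c0 <- (1 - al) - c1           # weight of the older sample
  # I_i = al I_{i-1} + c1 p_i + c0 p_{i-1}; I_1 = p_1 (constant pre-record)
  x <- c1 * p[-1L] + c0 * p[-n]
  I <- c(p[1], as.numeric(stats::filter(x, al, method = "recursive",
                                        init = p[1])))
  I - p
}
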