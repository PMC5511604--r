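#' Detector configuration
#'
#' Tunable parameters of the reflection-kernel fit.
#'
#' @param tau_expected Expected order of magnitude of the characteristic time
#'   tau (s); sets the high-pass width delta = 6 tau_expected.  The fit is
#'   not sensitive to this choice.
#' @param period Pulse/heartbeat period T (s); the fit window length is
#'   `window_fraction * period`.
#' @param window_fraction Fraction of the period used as fit-window width
#'   (default 1/3).
#' @param dt_range Search range for the round-trip lag Delta t (s),
#'   c(lo, hi).
#' @param tau_range Search range for tau (s), c(lo, hi).
#' @param threshold Pulse-onset threshold as a fraction of the peak smoothed
#'   upstroke.
#' @param mode "pressure" (separate then fit the backward wave) or
#'   "velocity" (fit the filtered velocity against its own echo).
#' @param highpass Apply the Gaussian high-pass to the fit target?  Needed
#'   when reflections from the rest of the network contaminate the record
#'   (arterial networks); unnecessary for a clean single-pulse rig, where
#'   it would also remove most of the slow aneurysm echo.
#' @param n_tau Number of log-spaced tau grid points in the coarse search.
#' @param t0 Optional known pulse-onset time (s); detected automatically
#'   when NULL.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(tau_expected = 0.02, period = 1,
                            window_fraction = 1 / 3,
                            dt_range = c(0.01, 0.3),
                            tau_range = c(1e-3, 0.3),
                            threshold = 0.2,
                            mode = c("pressure", "velocity"),
                            highpass = TRUE, n_tau = 30L, t0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(tau_expected > 0, period > 0,
            window_fraction > 0, window_fraction <= 1,
            length(dt_range) == 2L, all(dt_range >= 0), diff(dt_range) > 0,
            length(tau_range) == 2L, all(tau_range > 0), diff(tau_range) > 0,
            threshold > 0, threshold < 1)
  structure(list(tau_expected = tau_expected, period = period,
                 window_fraction = window_fraction, dt_range = dt_range,
                 tau_range = tau_range, threshold = threshold, mode = mode,
                 highpass = isTRUE(highpass), n_tau = as.integer(n_tau),
                 t0 = t0),
            class = "detector_config")
}

#' Detect the onset of the main pulse
#'
#' Finds the first crossing of `threshold * max` on the Gaussian-smoothed
#' derivative of the waveform and back-projects along that slope to the
#' baseline level, giving the pulse foot time.
#'
#' @param w A [waveform()] containing one dominant upstroke.
#' @param threshold Fraction of the peak smoothed derivative (0-1).
#' @param baseline_window Initial window (s) defining the baseline level.
#' @return Onset time t0 (s).
#' @export
detect_pulse_start <- function(w, threshold = 0.2, baseline_window = 0.05) {
  stopifnot(inherits(w, "waveform"), threshold > 0, threshold < 1)
  v <- w$values
  dt <- w$dt
  d <- diff(v) / dt
  k <- .gauss_kernel(max(2 * dt, 4e-3), dt)
  half <- (length(k) - 1L) %/% 2L
  pad <- min(half, length(d) - 1L)
  ext <- c(rep(d[1], half), d, rep(d[length(d)], half))
  ds <- as.numeric(stats::filter(ext, k, method = "convolution", sides = 2))
  ds <- ds[half + seq_along(d)]
  peak <- max(ds)
  nb <- max(2L, min(length(v), round(baseline_window / dt)))
  base <- mean(v[seq_len(nb)])
  noise <- stats::sd(v[seq_len(nb)])
  # dominant upstroke: excursion well above the baseline noise floor
  if (!(peak > 0) || (max(v) - base) <= 8 * noise)
    stop("detect_pulse_start: no dominant upstroke found")
  icross <- which(ds >= threshold * peak)[1]
  slope <- ds[icross]
  t_cross <- w$t_start + (icross - 0.5) * dt     # derivative sample midpoint
  v_cross <- (v[icross] + v[icross + 1L]) / 2
  t0 <- t_cross - (v_cross - base) / slope
  max(t0, w$t_start)
}

#' Fit the reflection kernel to a target waveform
#'
#' Minimizes the windowed least-squares functional
#' int_[t1, t2] (target - forward*R(.; tau, Dt) - B)^2 dt over the three
#' parameters (tau, Dt, B), with t1 = t0 + Dt and t2 = t1 + window.  The
#' background level B is linear and solved in closed form at each (tau, Dt);
#' the search is a deterministic coarse grid (Dt in steps of one sample, tau
#' log-spaced) followed by a Nelder-Mead polish with fractional-sample lags.
#'
#' @param forward Source [waveform()] to be convolved with the kernel.
#' @param target Target [waveform()] (already high-pass filtered), co-sampled
#'   with `forward`.
#' @param config A [detector_config()].
#' @return List of class `kernel_fit` with `tau`, `dt_lag`, `B`, `residual`
#'   (L2 over the window), `window` = c(t1, t2), `t0`, and `flat` (TRUE when
#'   the target had no variance and only B was fitted).
#' @export
fit_kernel <- function(forward, target, config = detector_config()) {
  stopifnot(inherits(forward, "waveform"), inherits(target, "waveform"),
            inherits(config, "detector_config"))
  if (length(forward) != length(target) ||
      abs(forward$dt - target$dt) > 1e-12)
    stop("fit_kernel: forward and target must be co-sampled")
  dt <- forward$dt
  n <- length(forward)
  t_end <- forward$t_start + (n - 1L) * dt
  t0 <- if (!is.null(config$t0)) config$t0 else
    detect_pulse_start(forward, config$threshold)
  win <- config$window_fraction * config$period
  # admissible integer lags: window must fit inside the record
  lag_lo <- max(config$dt_range[1], 0)
  lag_hi <- min(config$dt_range[2], t_end - win - t0)
  if (lag_hi < lag_lo)
    stop("fit_kernel: degenerate fit window (t2 beyond record for all lags)")
  lags <- seq(ceiling(lag_lo / dt), floor(lag_hi / dt)) * dt
  if (!length(lags)) lags <- lag_lo
  taus <- exp(seq(log(config$tau_range[1]), log(config$tau_range[2]),
                  length.out = config$n_tau))
  tv <- target$values
  window_idx <- function(lag) {
    i1 <- max(1L, 1L + round((t0 + lag - forward$t_start) / dt))
    i2 <- min(n, i1 + round(win / dt))
    i1:i2
  }
  # flat target: B-only fit
  idx_probe <- window_idx(lags[1])
  if (stats::sd(tv[idx_probe]) == 0 && all(tv == tv[1])) {
    return(structure(list(tau = NA_real_, dt_lag = NA_real_, B = tv[1],
                          residual = 0, window = t0 + c(lags[1], lags[1] + win),
                          t0 = t0, flat = TRUE),
                     class = "kernel_fit"))
  }
  sse_for <- function(g, lag) {      # g: zero-lag response; integer/frac lag
    conv <- .fft_delay(g, dt, lag)
    idx <- window_idx(lag)
    r <- tv[idx] - conv[idx]
    B <- mean(r)
    sum((r - B)^2) * dt
  }
  best <- list(sse = Inf)
  fv <- forward$values
  for (tau in taus) {
    g <- .reflect_zero_lag(fv, dt, tau)
    for (lag in lags) {
      s <- sse_for(g, lag)
      if (s < best$sse) best <- list(sse = s, tau = tau, lag = lag)
    }
  }
  # local polish over (log tau, lag) with fractional-sample lags
  obj <- function(par) {
    tau <- exp(par[1]); lag <- par[2]
    if (tau < config$tau_range[1] / 2 || tau > config$tau_range[2] * 2 ||
        lag < lag_lo || lag > lag_hi) return(.Machine$double.xmax)
    sse_for(.reflect_zero_lag(fv, dt, tau), lag)
  }
  op <- stats::optim(c(log(best$tau), best$lag), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 400))
  if (op$value <= best$sse) {
    tau <- exp(op$par[1]); lag <- op$par[2]; sse <- op$value
  } else {
    tau <- best$tau; lag <- best$lag; sse <- best$sse
  }
  conv <- .fft_delay(.reflect_zero_lag(fv, dt, tau), dt, lag)
  idx <- window_idx(lag)
  B <- mean(tv[idx] - conv[idx])
  structure(list(tau = tau, dt_lag = lag, B = B,
                 residual = sqrt(sse), window = t0 + c(lag, lag + win),
                 t0 = t0, flat = FALSE,
                 grid_sse = best$sse, sse = sse),
            class = "kernel_fit")
}

#' Convert fitted kernel parameters to aneurysm parameters
#'
#' Delta C_A = 2 A0 tau / (rho c0); K = 2 c0 tau / L_A; x_A = c0 Dt / 2.
#'
#' @param tau Fitted characteristic time (s).
#' @param dt_lag Fitted round-trip lag (s).
#' @param A0 Lumen area at the measurement site (m^2).
#' @param rho Fluid density (kg m^-3).
#' @param c0 Pulse-wave speed used for the conversion (m s^-1).
#' @param L_A_assumed Assumed aneurysm length (m) for the K conversion.
#' @return List with `dCA` (m^3 Pa^-1), `K`, `x_A` (m).
#' @export
convert_kernel_params <- function(tau, dt_lag, A0, rho, c0, L_A_assumed) {
  stopifnot(A0 > 0, rho > 0, c0 > 0, L_A_assumed > 0)
  list(dCA = 2 * A0 * tau / (rho * c0),
       K = 2 * c0 * tau / L_A_assumed,
       x_A = c0 * dt_lag / 2)
}

.detection_result <- function(fit, conv, config, site) {
  structure(c(fit[c("tau", "dt_lag", "B", "residual", "window", "t0")],
              conv, list(config = config, site = site)),
            class = "detection_result")
}

#' Detect an aneurysm from co-sited pressure and velocity waveforms
#'
#' Pipeline: separate forward/backward waves, Gaussian high-pass the backward
#' wave (delta = 6 tau_expected), fit the reflection kernel of the forward
#' wave to it, and convert (tau, Dt) to excess compliance and distance.
#'
#' @param p,u Co-sited pressure and velocity [waveform()]s.
#' @param site_params List with `rho` (kg m^-3), `c0` (m s^-1), `A0` (m^2)
#'   and optionally `L_A_assumed` (m; default 0.09).
#' @param config A [detector_config()].
#' @return Object of class `detection_result` with fitted `tau`, `dt_lag`,
#'   `B`, `residual`, and derived `dCA`, `K`, `x_A`.
#' @export
detect_from_pressure <- function(p, u, site_params,
                                 config = detector_config()) {
  stopifnot(all(c("rho", "c0", "A0") %in% names(site_params)))
  sep <- separate_waves(p, u, site_params$rho, site_params$c0)
  pb_f <- if (config$highpass)
    gaussian_highpass(sep$p_b, 6 * config$tau_expected) else sep$p_b
  if (is.null(config$t0))
    config$t0 <- detect_pulse_start(sep$p_f, config$threshold)
  fit <- fit_kernel(sep$p_f, pb_f, config)
  L_A <- if (!is.null(site_params$L_A_assumed)) site_params$L_A_assumed else 0.09
  conv <- convert_kernel_params(fit$tau, fit$dt_lag, site_params$A0,
                                site_params$rho, site_params$c0, L_A)
  .detection_result(fit, conv, config, p$site)
}

#' Detect an aneurysm from a single velocity waveform
#'
#' For sites where wave separation is impossible (the forward pulse and the
#' aneurysm echo travel together, e.g. a carotid branch): high-pass the
#' velocity, then fit `u' * R + B` to `u'` itself over the moving window.
#' The fitted lag is the round trip from the branch inlet to the aneurysm.
#'
#' @param u Velocity (or flow) [waveform()].
#' @param site_params As in [detect_from_pressure()].
#' @param config A [detector_config()] (mode "velocity").
#' @return `detection_result`.
#' @export
detect_from_velocity <- function(u, site_params,
                                 config = detector_config(mode = "velocity")) {
  stopifnot(all(c("rho", "c0", "A0") %in% names(site_params)))
  uf <- if (config$highpass)
    gaussian_highpass(u, 6 * config$tau_expected) else u
  if (is.null(config$t0))
    config$t0 <- detect_pulse_start(u, config$threshold)
  fit <- fit_kernel(uf, uf, config)
  L_A <- if (!is.null(site_params$L_A_assumed)) site_params$L_A_assumed else 0.09
  conv <- convert_kernel_params(fit$tau, fit$dt_lag, site_params$A0,
                                site_params$rho, site_params$c0, L_A)
  .detection_result(fit, conv, config, u$site)
}

#' @export
print.detection_result <- function(x, ...) {
  cat("Aneurysm detection result at", x$site, "\n")
  cat(sprintf("  tau    = %.3f ms\n", x$tau * 1e3))
  cat(sprintf("  Dt     = %.3f ms  ->  x_A = %.1f cm\n",
              x$dt_lag * 1e3, x$x_A * 1e2))
  cat(sprintf("  dC_A   = %.3g m^3/Pa (%.3g cm^3/MPa)\n", x$dCA, x$dCA * 1e12))
  cat(sprintf("  K      = %.3g (assumed L_A)\n", x$K))
  cat(sprintf("  B      = %.3g, residual = %.3g, window = [%.3f, %.3f] s\n",
              x$B, x$residual, x$window[1], x$window[2]))
  invisible(x)
}
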