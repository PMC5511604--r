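# synthetic forward pulse resembling the rig pressure waveform
synth_forward <- function(dt = 1e-3, dur = 0.9) {
  t <- seq(0, dur, by = dt)
  v <- 25 * (exp(-((t - 0.15) / 0.035)^2) + 0.5 * exp(-((t - 0.28) / 0.08)^2))
  waveform(v, dt = dt, quantity = "pressure")
}

synth_cfg <- function(...) {
  detector_config(tau_expected = 0.01, period = 0.6, threshold = 0.1,
                  dt_range = c(0.03, 0.1), tau_range = c(1e-3, 0.1),
                  highpass = FALSE, ...)
}

test_that("pulse-onset detection finds the foot of a half-sine and rejects noise", {
  dt <- 2e-3
  t <- seq(0, 1, by = dt)
  v <- ifelse(t >= 0.1 & t <= 0.3, sin(pi * (t - 0.1) / 0.2), 0)
  w <- waveform(v, dt = dt, quantity = "pressure")
  t0 <- detect_pulse_start(w, 0.2)
  expect_equal(t0, 0.10, tolerance = 0.05)   # within 5 ms
  expect_lt(abs(t0 - 0.10), 0.005)
  # equivariance: a shifted copy shifts the onset equally
  v2 <- ifelse(t >= 0.35 & t <= 0.55, sin(pi * (t - 0.35) / 0.2), 0)
  t02 <- detect_pulse_start(waveform(v2, dt = dt, quantity = "pressure"), 0.2)
  expect_equal(t02 - t0, 0.25, tolerance = 0.005)
  # pure noise raises an error
  set.seed(3)
  expect_error(detect_pulse_start(waveform(rnorm(500), dt = dt,
                                           quantity = "pressure"), 0.2),
               "upstroke")
})

test_that("noiseless kernel fits recover (tau, Dt) essentially exactly", {
  fwd <- synth_forward()
  for (par in list(c(0.020, 0.058), c(0.004, 0.045), c(0.060, 0.090))) {
    tgt <- reflect_convolve(fwd, par[1], par[2])
    fit <- fit_kernel(fwd, tgt, synth_cfg())
    expect_lt(abs(fit$tau - par[1]) / par[1], 0.01)
    expect_lt(abs(fit$dt_lag - par[2]), fwd$dt)
  }
})

test_that("fit residual at the optimum dominates the coarse grid", {
  fwd <- synth_forward()
  tgt <- reflect_convolve(fwd, 0.017, 0.064)
  tgt <- add_noise(tgt, 0.1, seed = 5)
  fit <- fit_kernel(fwd, tgt, synth_cfg())
  expect_lte(fit$sse, fit$grid_sse)
})

test_that("kernel fits tolerate noise and degrade monotonically with it", {
  fwd <- synth_forward()
  tau_s <- 0.020; lag_s <- 0.058
  clean <- reflect_convolve(fwd, tau_s, lag_s)
  # 5% noise, 20 seeds: average recovery within 10% (tau) and 2 samples (Dt)
  errs <- t(vapply(1:20, function(seed) {
    tgt <- add_noise(clean, 0.05, seed = seed)
    fit <- fit_kernel(fwd, tgt, synth_cfg())
    c(abs(fit$tau - tau_s) / tau_s, abs(fit$dt_lag - lag_s))
  }, c(0, 0)))
  expect_lt(mean(errs[, 1]), 0.10)
  expect_lt(mean(errs[, 2]), 2 * fwd$dt)
  # noise sweep: median tau error grows with the noise level
  lvls <- c(0.02, 0.1, 0.3, 0.6)
  med <- vapply(lvls, function(sg) {
    stats::median(vapply(1:6, function(seed) {
      fit <- fit_kernel(fwd, add_noise(clean, sg, seed = 100 + seed),
                        synth_cfg())
      abs(fit$tau - tau_s) / tau_s
    }, 0))
  }, 0)
  expect_gt(stats::cor(lvls, med, method = "spearman"), 0)
})

test_that("fits are scale-equivariant and handle degenerate targets", {
  fwd <- synth_forward()
  tgt <- reflect_convolve(fwd, 0.02, 0.058)
  tgt$values <- tgt$values + 1.5          # constant background
  f1 <- fit_kernel(fwd, tgt, synth_cfg())
  sc <- wf_with(tgt, 40 * tgt$values)
  f2 <- fit_kernel(wf_with(fwd, 40 * fwd$values), sc, synth_cfg())
  expect_equal(f2$tau, f1$tau, tolerance = 1e-4)
  expect_equal(f2$dt_lag, f1$dt_lag, tolerance = 1e-6)
  expect_equal(f2$B, 40 * f1$B, tolerance = 1e-3)
  # flat target: B-only fit, tau flagged undefined
  flat <- wf_with(tgt, rep(2.2, length(tgt)))
  ff <- fit_kernel(fwd, flat, synth_cfg())
  expect_true(ff$flat)
  expect_true(is.na(ff$tau))
  expect_equal(ff$B, 2.2)
  # window beyond the record
  short_cfg <- synth_cfg()
  short_cfg$dt_range <- c(0.85, 0.9)
  expect_error(fit_kernel(fwd, tgt, short_cfg), "window")
})

test_that("parameter conversion reproduces the aortic reference arithmetic", {
  # tau = 35 ms at segment-45 conditions gives K = 2.94 back
  cv <- convert_kernel_params(35.0e-3, 57.9e-3, A0 = pi * 6.775e-3^2,
                              rho = 1040, c0 = 4.36, L_A_assumed = 0.104)
  expect_equal(cv$K, 2.94, tolerance = 0.005)
  # dCA = 2 A0 tau / (rho c0), independent arithmetic oracle
  expect_equal(cv$dCA, 2 * (pi * 6.775e-3^2) * 35.0e-3 / (1040 * 4.36),
               tolerance = 1e-12)
  expect_equal(cv$dCA, 2.226e-9, tolerance = 1e-3)
  # x_A = c0 Dt / 2: the rig reference distance with the 19 m/s convention
  cv2 <- convert_kernel_params(2.62e-3, 57.9e-3, A0 = pi * 8.5e-3^2,
                               rho = 1000, c0 = 19.0, L_A_assumed = 0.09)
  expect_equal(cv2$x_A, 0.550, tolerance = 0.001)
})

test_that("velocity-mode detection recovers an injected echo", {
  # compact pulse whose echo window does not overlap the pulse itself:
  # the configuration the carotid-waveform method assumes
  dt <- 1e-3
  t <- seq(0, 0.9, by = dt)
  base <- 0.4 * exp(-((t - 0.15) / 0.025)^2)
  tau_s <- 0.012; lag_s <- 0.16
  u0 <- waveform(base, dt = dt, quantity = "velocity")
  echo <- reflect_convolve(u0, tau_s, lag_s)
  u <- wf_with(u0, base + echo$values)
  cfg <- detector_config(tau_expected = 0.01, period = 0.6, threshold = 0.1,
                         dt_range = c(0.10, 0.25), tau_range = c(1e-3, 0.1),
                         highpass = FALSE, mode = "velocity")
  det <- detect_from_velocity(u, list(rho = 1040, c0 = 4.9, A0 = 3e-5,
                                      L_A_assumed = 0.104), cfg)
  # the echo itself perturbs the source used in the fit, so allow 10% / 2 dt
  expect_lt(abs(det$tau - tau_s) / tau_s, 0.10)
  expect_lt(abs(det$dt_lag - lag_s), 2 * dt)
  expect_equal(det$x_A, 4.9 * det$dt_lag / 2, tolerance = 1e-12)
})

test_that("fitted tau is only mildly sensitive to the window fraction", {
  rs <- rig_sim(44)
  s <- rs$sim$sites[["main-proximal@0.04"]]
  sp <- rig_site_params(rs$fx)
  taus <- vapply(c(1 / 4, 1 / 3, 1 / 2), function(fw) {
    # period scaled so the longest window still ends before the distal echo
    cfg <- rig_detector_config(window_fraction = fw)
    cfg$period <- 0.35 / (3 * fw)
    detect_from_pressure(s$p, s$u, sp, cfg)$tau
  }, 0)
  expect_lt(diff(range(taus)) / stats::median(taus), 0.25)
})
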