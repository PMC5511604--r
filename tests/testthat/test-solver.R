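# small helper networks
single_tube <- function(L = 3, a = 8.5e-3, E = 2.8e6, mu = 0, inflow,
                        terminal = terminal_bc("nonreflecting"),
                        monitors = list(list(segment = "tube", s = 0.5))) {
  seg <- vessel_segment("tube", L, a, a, 2e-3, E, 0.5)
  vessel_network(list(seg), list(),
                 inlet = list(segment = "tube", end = "L",
                              bc = inflow),
                 terminals = list(list(segment = "tube", end = "R",
                                       bc = terminal)),
                 fluid = fluid_properties(1000, mu), monitors = monitors)
}

gauss_inlet <- function(amp = 0.005, t0 = 0.06, w = 0.015) {
  inlet_bc(function(t) amp * exp(-((t - t0) / w)^2), "velocity")
}

test_that("discretization counts nodes, samples bumps, and refuses coarse grids", {
  net <- single_tube(L = 2, inflow = gauss_inlet())
  mesh <- discretize(net, dx = 0.01)
  expect_equal(mesh$segments[[1]]$n, 201L)
  # aneurysm bump sampled at 1 mm reproduces the peak radius at midpoint
  seg <- vessel_segment("an", 0.14, 8.5e-3, 8.5e-3, 2e-3, 2.8e6, 0.5,
                        aneurysm = list(kind = "arc", x1 = 0.025, L_A = 0.09,
                                        D = 50e-3, R_s = 0.01))
  net2 <- vessel_network(list(seg), list(),
                         inlet = list(segment = "an", end = "L",
                                      bc = gauss_inlet()),
                         terminals = list(list(segment = "an", end = "R",
                                               bc = terminal_bc("nonreflecting"))),
                         fluid = fluid_properties(1000, 0), monitors = list())
  mesh2 <- discretize(net2, dx = 1e-3)
  expect_equal(max(sqrt(mesh2$segments[[1]]$A0 / pi)), 25e-3, tolerance = 1e-3)
  expect_error(discretize(net2, dx = 0.1), "an")
})

test_that("a resting network with nonuniform geometry stays exactly at rest", {
  seg <- vessel_segment("an", 0.2, 8e-3, 6e-3, 2e-3, 2.8e6, 0.5,
                        aneurysm = list(kind = "cosine", x1 = 0.05,
                                        L_A = 0.1, k_delta = 1))
  net <- vessel_network(list(seg), list(),
                        inlet = list(segment = "an", end = "L",
                                     bc = inlet_bc(function(t) 0, "velocity")),
                        terminals = list(list(segment = "an", end = "R",
                                              bc = terminal_bc("nonreflecting"))),
                        fluid = fluid_properties(1000, 1e-3),
                        monitors = list(list(segment = "an", s = 0.5)))
  sim <- run_simulation(net, duration = 0.05, dx = 2e-3, cfl = 0.5)
  expect_lt(max(abs(sim$sites[[1]]$u$values)), 1e-12)
  expect_lt(max(abs(sim$sites[[1]]$p$values)), 1e-9)
})

test_that("small-amplitude inviscid pulses follow the d'Alembert solution", {
  # two monitors 50 diameters apart: delayed copy, speed c0, no decay
  net <- single_tube(L = 3, inflow = gauss_inlet(amp = 0.005),
                     monitors = list(list(segment = "tube", s = 0.1),
                                     list(segment = "tube", s = 0.1 + 0.85 / 3)))
  sim <- run_simulation(net, duration = 0.22, dx = 0.005, cfl = 0.5,
                        out_dt = 2e-4)
  c0 <- wave_speed(8.5e-3, 2e-3, 2.8e6, 0.5, 1000)
  p1 <- sim$sites[[1]]$p$values
  p2 <- sim$sites[[2]]$p$values
  lagn <- round(0.85 / c0 / 2e-4)
  shifted <- c(rep(0, lagn), p1)[seq_along(p2)]
  expect_lt(max(abs(p2 - shifted)), 0.01 * max(p1))     # < 1% L-inf
  expect_lt(abs(max(p2) / max(p1) - 1), 0.01)           # < 1% decay
  # measured speed from peak alignment within 1%
  dtpk <- (which.max(p2) - which.max(p1)) * 2e-4
  expect_lt(abs(0.85 / dtpk - c0) / c0, 0.01)
  # forward-wave impedance relation p = rho c0 u within 2%
  u1 <- sim$sites[[1]]$u$values
  i <- which.max(p1)
  expect_lt(abs(p1[i] - 1000 * c0 * u1[i]) / p1[i], 0.02)
})

test_that("viscous steady flow reproduces the Poiseuille pressure drop", {
  a <- 6e-3; L <- 0.5; mu <- 1e-3; u0 <- 0.1
  c0 <- wave_speed(a, 2e-3, 2.8e8, 0.5, 1000)
  ramp <- inlet_bc(function(t) u0 * min(t / 0.02, 1), "velocity")
  net <- single_tube(L = L, a = a, E = 2.8e8, mu = mu, inflow = ramp,
                     terminal = terminal_bc("windkessel",
                                            R1 = 1000 * c0 / (pi * a^2),
                                            R2 = 0, C = 0),
                     monitors = list(list(segment = "tube", s = 0),
                                     list(segment = "tube", s = 1)))
  sim <- run_simulation(net, duration = 0.3, dx = 0.01, cfl = 0.5)
  n <- length(sim$sites[[1]]$p)
  late <- (n - 20):n
  dp <- mean(sim$sites[[1]]$p$values[late] - sim$sites[[2]]$p$values[late])
  expect_equal(dp, 8 * pi * mu * L * u0 / (pi * a^2), tolerance = 0.03)
})

test_that("junctions are transparent when impedance-matched and conserve mass", {
  a <- 8.5e-3
  s1 <- vessel_segment("s1", 1.5, a, a, 2e-3, 2.8e6, 0.5)
  s2 <- vessel_segment("s2", 1.5, a, a, 2e-3, 2.8e6, 0.5)
  net <- vessel_network(list(s1, s2), list(c("s1:R", "s2:L")),
                        inlet = list(segment = "s1", end = "L",
                                     bc = gauss_inlet(amp = 0.01, t0 = 0.04,
                                                      w = 0.008)),
                        terminals = list(list(segment = "s2", end = "R",
                                              bc = terminal_bc("nonreflecting"))),
                        fluid = fluid_properties(1000, 0),
                        monitors = list(list(segment = "s1", s = 0.5)))
  sim <- run_simulation(net, duration = 0.25, dx = 0.005, cfl = 0.5,
                        out_dt = 2e-4)
  tt <- wf_time(sim$sites[[1]]$p)
  v <- sim$sites[[1]]$p$values
  inc <- max(v[tt < 0.1])
  refl <- max(abs(v[tt > 0.12]))
  expect_lt(refl / inc, 0.005)
  # global volume balance
  vol <- sim$volume
  expect_lt(abs(vol$injected - vol$outflow - vol$stored) / vol$injected, 0.005)
})

test_that("matched Windkessel terminals absorb; unloaded RCR reaches its steady state", {
  a <- 8.5e-3
  c0 <- wave_speed(a, 2e-3, 2.8e6, 0.5, 1000)
  Zc <- 1000 * c0 / (pi * a^2)
  # matched R1, C = 0, R2 = 0: reflection < 1%
  net <- single_tube(L = 3, inflow = gauss_inlet(amp = 0.01, t0 = 0.05,
                                                 w = 0.01),
                     terminal = terminal_bc("windkessel", R1 = Zc, R2 = 0,
                                            C = 0))
  sim <- run_simulation(net, duration = 0.35, dx = 0.01, cfl = 0.5)
  tt <- wf_time(sim$sites[[1]]$p)
  v <- sim$sites[[1]]$p$values
  expect_lt(max(abs(v[tt > 0.22])) / max(v), 0.01)
  # constant inflow through an RCR: outlet pressure -> Q (R1 + R2)
  a2 <- 6e-3
  c2 <- wave_speed(a2, 2e-3, 2.8e8, 0.5, 1000)
  Z2 <- 1000 * c2 / (pi * a2^2)
  ramp <- inlet_bc(function(t) 0.05 * min(t / 0.02, 1), "velocity")
  net2 <- single_tube(L = 0.5, a = a2, E = 2.8e8, inflow = ramp,
                      terminal = terminal_bc("windkessel", R1 = Z2,
                                             R2 = 3 * Z2, C = 1e-11),
                      monitors = list(list(segment = "tube", s = 1)))
  sim2 <- run_simulation(net2, duration = 0.4, dx = 0.01, cfl = 0.5)
  pQ <- sim2$sites[[1]]
  n <- length(pQ$p)
  expect_equal(mean(pQ$p$values[(n - 20):n]),
               mean(pQ$q$values[(n - 20):n]) * (Z2 + 3 * Z2),
               tolerance = 0.02)
})

test_that("monitored waveforms converge at second order under grid refinement", {
  sims <- lapply(c(0.02, 0.01, 0.005), function(dx) {
    net <- single_tube(L = 3, inflow = gauss_inlet(amp = 0.005))
    run_simulation(net, duration = 0.18, dx = dx, cfl = 0.5, out_dt = 5e-4)
  })
  p <- lapply(sims, function(s) s$sites[[1]]$p$values)
  e1 <- sqrt(mean((p[[1]] - p[[2]])^2))
  e2 <- sqrt(mean((p[[2]] - p[[3]])^2))
  expect_gt(e1 / e2, 3)   # ~4 for a second-order interior scheme
})

test_that("area steps reflect according to linear transmission-line theory", {
  a1 <- 8.5e-3; a2 <- 6.0e-3
  s1 <- vessel_segment("s1", 1.5, a1, a1, 2e-3, 2.8e6, 0.5)
  s2 <- vessel_segment("s2", 1.5, a2, a2, 2e-3, 2.8e6, 0.5)
  net <- vessel_network(list(s1, s2), list(c("s1:R", "s2:L")),
                        inlet = list(segment = "s1", end = "L",
                                     bc = gauss_inlet(amp = 0.005, t0 = 0.04,
                                                      w = 0.008)),
                        terminals = list(list(segment = "s2", end = "R",
                                              bc = terminal_bc("nonreflecting"))),
                        fluid = fluid_properties(1000, 0),
                        monitors = list(list(segment = "s1", s = 0.5)))
  sim <- run_simulation(net, duration = 0.2, dx = 0.005, cfl = 0.5,
                        out_dt = 2e-4)
  tt <- wf_time(sim$sites[[1]]$p)
  v <- sim$sites[[1]]$p$values
  inc <- max(v[tt < 0.1]); refl <- max(v[tt >= 0.12])
  c1 <- wave_speed(a1, 2e-3, 2.8e6, 0.5, 1000)
  c2 <- wave_speed(a2, 2e-3, 2.8e6, 0.5, 1000)
  Y1 <- pi * a1^2 / (1000 * c1); Y2 <- pi * a2^2 / (1000 * c2)
  expect_equal(refl / inc, (Y1 - Y2) / (Y1 + Y2), tolerance = 0.02)
})
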