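# hemowave

Simulation and detection of fusiform aneurysms from pulse-wave
reflections, in one-dimensional compliant-tube networks.

An abdominal aortic aneurysm is usually silent until it ruptures, and
population screening by imaging is expensive. A fusiform dilation of a
vessel, however, leaves a signature in the pressure and velocity
waveforms that pass it: because pulse wavelengths (metres) dwarf aneurysm
lengths (centimetres), the bulge acts as a single lumped *excess
compliance* and reflects a characteristic echo. `hemowave` is for
researchers in cardiovascular biomechanics who want to study — entirely
in silico — whether that echo can reveal where an aneurysm is and how
severe it is.

The package provides the full pipeline:

* a 1D fluid–structure solver for networks of elastic tubes
  (`run_simulation()`): continuity + momentum with the tube law
  $p = p_{ext} + \beta(\sqrt{A}-\sqrt{A_0})$, Poiseuille friction,
  characteristic inlet/junction boundary conditions and three-element
  Windkessel terminals;
* aneurysm geometry and its lumped parameters (`arc_aneurysm_radius()`,
  `cosine_aneurysm_radius()`, `compute_K()`, `excess_compliance()`):

  $$K = \frac{1}{L_A}\int_0^{L_A}\Big(\frac{a_A^3}{a_v^3}-1\Big)dx,
  \qquad \tau = \frac{\rho c_0}{2A_0}\Delta C_A = \frac{L_A}{2c_0}K,
  \qquad \Delta t = \frac{2x_A}{c_0};$$

* linear wave separation $p_{f,b} = \tfrac12(p \pm \rho c_0 u)$, Gaussian
  high-pass filtering, and the aneurysm reflection kernel
  $R(t) = -\delta(t-\Delta t) + H(t-\Delta t)\,\tau^{-1}e^{-(t-\Delta t)/\tau}$
  (`separate_waves()`, `gaussian_highpass()`, `reflect_convolve()`);
* the detector (`detect_from_pressure()`, `detect_from_velocity()`): a
  deterministic least-squares fit of $p_f * R + B$ to the (filtered)
  backward wave over a moving window, returning $\tau$, $\Delta t$ and the
  derived severity $\Delta C_A = 2A_0\tau/(\rho c_0)$ and location
  $x_A = c_0\Delta t/2$;
* synthetic study set-ups (`build_rig()`, `build_aorta_chain()`): a
  laboratory latex-tube rig with arc-shaped aneurysm phantoms
  (24–50 mm peak diameter), and a reduced aortic chain with cosine-bump
  aneurysms doubling (AAA-2) or tripling (AAA-3) the lumen radius.

## Worked example

Simulate one pump stroke through the rig carrying the largest phantom,
then recover the aneurysm from the waveforms 2 cm into the main tube:

```r
library(hemowave)

fx  <- build_rig(50)                       # 50 mm peak-diameter phantom
fx$ground_truth$tau * 1e3                  # 27.2 ms  (geometric tau)
fx$ground_truth$x_A                        # 0.55 m   (site -> bump centre)

sim <- run_simulation(fx$network, duration = 0.5, dx = 0.01, cfl = 0.8)
s   <- sim$sites[["main-proximal@0.04"]]   # the 2 cm monitoring site

det <- detect_from_pressure(
  s$p, s$u,
  site_params = list(rho = 1000, c0 = fx$ground_truth$c0,
                     A0 = pi * 0.0085^2, L_A_assumed = 0.09),
  config = detector_config(tau_expected = 0.01, period = 0.35,
                           threshold = 0.1, dt_range = c(0.02, 0.12),
                           tau_range = c(5e-4, 0.1), highpass = FALSE))
det
#> Aneurysm detection result at main-proximal@0.04
#>   tau    = 30.510 ms
#>   Dt     = 48.483 ms  ->  x_A = 50.8 cm
#>   dC_A   = 6.61e-10 m^3/Pa (661 cm^3/MPa)
#>   K      = 14.2 (assumed L_A)
#>   B      = 1.43e+03, residual = 2.57e+03, window = [0.131, 0.248] s
```

The fitted round-trip lag places the aneurysm at 51 cm (true: 55 cm, a
-7% bias because reflection starts at the proximal neck of the bulge),
and the fitted characteristic time 30.5 ms sits just above the geometric
27.2 ms — the lumped kernel ignores the bulge's reduced inertance, so
fits systematically exceed the compliance-only reference. Across the
four phantoms the fitted tau ordering reproduces the severity ordering
exactly.

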