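---
title: "Detecting fusiform aneurysms from pulse-wave reflections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusiform aneurysms from pulse-wave reflections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

## The model

`hemowave` treats an artery (or a laboratory latex tube) as a 1D compliant
tube carrying an incompressible fluid.  The state is the lumen area $A(x,t)$
and the cross-sectionally averaged velocity $u(x,t)$, governed by

$$A_t + (Au)_x = 0, \qquad
  u_t + \left(\tfrac{u^2}{2} + \tfrac{p}{\rho}\right)_x
      = -\frac{8\pi\mu u}{\rho A},$$

closed by the thin-wall tube law
$p = p_\mathrm{ext} + \beta(\sqrt{A} - \sqrt{A_0})$ with
$\beta = \sqrt{\pi}\,h E' / A_0$ and $E' = E/(1-\sigma^2)$.  The friction
source assumes a Poiseuille profile.  Small disturbances travel at

$$c_0 = \sqrt{\frac{h E'}{2 \rho a_0}},$$

about 21 m/s in the laboratory tube (17 mm bore, 2 mm latex wall,
$E = 2.8$ MPa) and 4–5 m/s in the aorta.

A fusiform aneurysm is a localized widening $a_A(x) \ge a_v(x)$ of the
lumen.  Because pulse wavelengths (metres) far exceed aneurysm lengths
(centimetres), the bump acts on the wave as a single lumped element whose
strength is its *excess compliance*

$$\Delta C_A = \int_0^{L_A}
   \left(\frac{2\pi a_A^3}{E'_A h_A} - \frac{2\pi a_v^3}{E'_v h_v}\right)
   \mathrm{d}x,
  \qquad
  K = \frac{1}{L_A}\int_0^{L_A}
      \left(\frac{a_A^3(x)}{a_v^3(x)} - 1\right)\mathrm{d}x,$$

$K$ being the excess compliance relative to a healthy vessel of the same
length when wall stiffness is uniform.  A lumped compliance at distance
$x_A$ reflects an incident wave with frequency response

$$R(\omega) = \frac{i\omega\tau}{1 - i\omega\tau}\, e^{i\omega\,\Delta t},
 \qquad
 \tau = \frac{\rho c_0}{2 A_0}\,\Delta C_A = \frac{L_A}{2 c_0} K,
 \qquad \Delta t = \frac{2 x_A}{c_0},$$

whose impulse response is
$R(t) = -\delta(t - \Delta t) + H(t-\Delta t)\,\tau^{-1} e^{-(t-\Delta t)/\tau}$.
The *detector* inverts this: it fits $p_f * R(\cdot;\tau,\Delta t) + B$ to
the measured backward wave, and reads off severity
($\Delta C_A = 2 A_0 \tau / \rho c_0$) and location ($x_A = c_0 \Delta t/2$).

```{r k-values}
# compliance ratios of the two aortic cosine-bump aneurysms
compute_K(cosine_aneurysm_radius(1, 1, 0, 1), 1, 1)   # 47/16 = 2.94
compute_K(cosine_aneurysm_radius(1, 2, 0, 1), 1, 1)   # 10.0
tau_from_geometry(0.104, 4.36, 47 / 16)               # 35.0 ms
```

## The solver

`run_simulation()` integrates the $(A, u)$ system with a two-step
Richtmyer (Lax–Wendroff type) explicit scheme, second-order in the smooth
interior.  Boundary values are imposed through characteristic variables.
Three numerical choices deserve explanation.

* **Perturbation invariants at boundaries.**  The textbook Riemann
  invariants $u \pm 4c$ are constant along characteristics only in a
  uniform tube; on tapered geometry they drift even at rest.  All boundary
  extrapolation therefore uses $u \pm 4(c - c_0(x))$, which vanishes
  identically in any resting geometry.  This keeps a resting tapered
  vessel at rest to machine precision (asserted in the tests).

* **Sensor-scaled dissipation.**  An unlimited second-order scheme traps
  grid-scale oscillations inside large aneurysm bumps (the conjugation
  arcs of the laboratory phantoms are steep), which eventually blow up.  A
  pressure-curvature sensor (Jameson-style) adds diffusion proportional to
  the local non-smoothness, applied to the area *perturbation* $A - A_0$
  so the rest geometry is untouched.  The sensor is quadratic in solution
  curvature: a smooth pulse loses less than $10^{-4}$ of its amplitude
  over 50 tube diameters (asserted against the d'Alembert solution), while
  sawtooth modes are damped strongly.

* **Time step.**  $\Delta t = \mathrm{CFL}\cdot\min_i \Delta x_i /
  (m\,c_{0,i})$ with a speed-margin $m$ (default 1.4) covering the
  convective excess $|u| + c - c_0$; arterial flows reach $u \sim 0.5\,c$,
  so periodic aortic runs use $m = 1.7$.  A CFL audit runs every 50 steps.

Junctions impose flow conservation and total-pressure continuity
($p + \tfrac{1}{2}\rho u^2$; a static-pressure toggle exists for
sensitivity checks) via damped Newton iteration on the end areas.
Terminals are non-reflecting or three-element Windkessel (RCR) models,
integrated implicitly; with $R_1$ equal to the characteristic impedance
$\rho c_0/A_0$, $C = 0$, $R_2 = 0$, an arriving pulse is absorbed with
reflection below 1%.

Solver validation in the test suite covers: propagation speed and shape
preservation against the d'Alembert solution (< 1%), the area-step
reflection coefficient against $(Y_1 - Y_2)/(Y_1 + Y_2)$ (< 2%),
Poiseuille steady pressure drop, RCR steady states, global volume balance
(< 0.5% on a junction network), and second-order grid convergence.

## Synthetic study conditions

No measured data ship with the package; `build_rig()` and
`build_aorta_chain()` regenerate the two study set-ups from their printed
geometry, and all ground truths (K, $\Delta C_A$, $\tau$, $\Delta t$) are
recomputed from the geometry module at build time.

**Laboratory rig.**  A 2 m latex tube (ID 17 mm, wall 2 mm,
$E = 2.8$ MPa), a 14 cm aneurysm segment 50 cm from the inlet holding a
9 cm circular-arc bump (peak diameters 24/34/44/50 mm, conjugation radius
10 mm), rigid 12 mm fittings, a 6.5 m outlet line and a wide-tube
reservoir (10x area, non-reflecting).  Water is the working fluid; a
piston stroke injects 100 cm^3 in 0.6 s.  The Poisson ratio of the latex
is not reported; 0.5 (incompressible rubber) is assumed.  The measured
piston waveforms are load-dependent and two-humped with a steep first
rise; the generator emulates this with two raised-cosine humps (widths
0.09 s and 0.32 s), a shape choice, not a mechanical pump model.  The
"rigid" fittings are modelled as tube segments stiffened 100-fold
(wave speed ~210 m/s, ten times the main tube): for the long waves used
they are indistinguishable from ideal rigid pipes, and one scheme then
handles every segment.

**Reduced aortic chain.**  The fifteen monitored aortic segments (arch to
abdominal aorta V) in series, with two carotid-like branches at the arch;
wall thickness follows the empirical radius law (radius in cm), E = 225
kPa, sigma = 0.5, blood with rho = 1.04 g/cm^3, mu = 4 mPa s.  The
resulting per-segment mean wave speeds reproduce the published averaged
speeds (4.03–4.89 m/s) to a few percent.  The aneurysm is a cosine bump
spanning 10.4 cm of the 10.6 cm abdominal-aorta-IV segment, with radius
increment equal to (AAA-2) or twice (AAA-3) the local healthy radius.
All omitted side branches are absorbed into the three Windkessel
terminals: matched $R_1$, distal resistances splitting a net peripheral
resistance of 1.7e8 Pa s/m^3 as 70% abdominal / 15% per carotid, and
$R_2 C = 1.3$ s.  Inflow is a periodic sin^2 systolic ejection (85 cm^3
per 1 s beat over 0.3 s).  The rest geometry is referenced at mean
arterial pressure (`p_ext` = mean inflow x net resistance) and runs are
initialized there, which removes most of the slow Windkessel charging
transient.  This chain is an intentional reduction: it exercises the
detection method under network conditions (mixed reflections, periodic
flow) but does not reproduce the full arterial tree's fitted values.

What these fixtures do *not* emulate about real data: viscoelastic walls,
3D flow in the bulge, measurement noise spectra (only white noise is
provided), probe placement error, and the load feedback between reflected
waves and the heart.

## Detector choices

* The high-pass width is $\delta = 6\,\tau_\mathrm{expected}$; filtering
  is *optional* and off in the rig analyses.  In a single-pulse rig the
  record before the distal reflection is clean, and since the aneurysm
  echo inherits the (slow) timescale of the incident pulse, any high-pass
  aggressive enough to matter also removes the echo.  In the periodic
  network, reflections from the rest of the tree dominate, and filtering
  plus the background constant $B$ are what make the fit identifiable.
* The fit minimizes the windowed least squares over $(\tau, \Delta t, B)$
  with the window $[t_0 + \Delta t,\; t_0 + \Delta t + T/3]$ moving with
  the candidate lag; $B$ is solved in closed form, and the search is a
  deterministic coarse grid ($\Delta t$ in steps of one sample, 30
  log-spaced $\tau$ values) polished by Nelder–Mead with band-limited
  fractional-sample lags.  Detection is therefore bit-reproducible.
* Pulse onset $t_0$ is detected automatically from the smoothed
  derivative (threshold at 20% of the peak upstroke, back-projected to
  baseline).
* The exponential tail of the kernel is applied by the exact one-pole
  recursion for piecewise-linear input, stable for $\tau$ near the
  sampling interval; the delta term is an exact shifted copy.
* Pressures are referenced to the mean over the first 50 ms before
  separation.
* $c_0$ for separation and conversion is the healthy-vessel value from
  the geometry module at the monitoring site.

## Known limitations

* The lumped kernel keeps the aneurysm's excess *compliance* but ignores
  its reduced *inertance* (wider lumen, less fluid mass per unit length).
  Both scatter with the same sign at long wavelength, so fitted $\tau$
  systematically exceeds the compliance-only geometric $\tau$ — by about
  the ratio $(K + K_L)/K$ with
  $K_L = L_A^{-1}\int (1 - a_v^2/a_A^2)\,\mathrm{d}x$, i.e. +30–50% for
  the smaller phantoms and +5–10% for the largest.  The same excess
  appears in the original experimental study design, and the recovered
  severity ordering is unaffected, but point estimates of $\Delta C_A$
  inherit this bias, and waveform-level agreement between the simulated
  backward wave and the compliance-only kernel prediction plateaus near
  20% relative $L_2$ rather than the few percent a perfect lumped model
  would give.
* Fitted $\Delta t$ sits a few percent below $2 x_A / c_0$ because
  reflection begins at the proximal neck of the bump rather than its
  centre; the bias grows with bump size (about -5% to -8% across the four
  phantoms).
* The reduced aortic chain funnels 70% of the cardiac output through the
  abdominal outlet (no intervening branches), so velocities in the distal
  aorta exceed physiological values; this is a property of the reduction,
  not of the method.
* Windkessel parameters of the real arterial tree are not published in
  the source tables; the matched-impedance defaults are a modelling
  choice, and absolute pressures in the chain depend on them.
* The chain's whole-system RC time constant (arterial plus Windkessel
  compliance times net resistance) is about 2.4 s, longer than the three
  simulated beats, so the raw pressure keeps a slow near-DC
  equilibration tail between cycles (under 10% of pulse pressure with
  mean-pressure initialization).  The high-passed waveform the detector
  actually consumes is periodic to about 1% of pulse pressure by the
  third cycle; the tests assert both bounds.

## Problem sizes used in the shipped tests

Single-pulse rig runs use a 1 cm grid (about 1000 nodes, 18k time steps,
0.5 s of physical time); aortic-chain runs use a 1.6 mm grid (about 350
nodes, 20k steps, three 1 s cycles).  Detection grids span
$\Delta t \in [20, 120]$ ms (rig) or $[50, 300]$ ms (chain) at one-sample
resolution with 30 log-spaced $\tau$ values.  These sizes keep each
fixture's simulate-plus-detect round trip at roughly half a minute while
the validation tolerances above still hold.
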