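Package: hemowave
Title: One-Dimensional Pulse-Wave Simulation and Reflection-Based
    Aneurysm Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates pressure and velocity pulse waveforms in networks of
    compliant elastic tubes using a one-dimensional fluid-structure
    interaction model (continuity and momentum equations with a
    pressure-area closure), with characteristic-based inlet, junction and
    three-element Windkessel boundary conditions.  Provides linear
    forward/backward wave separation, Gaussian high-pass filtering and a
    lumped-compliance reflection kernel, and fits that kernel to measured
    or simulated waveforms to recover the location and excess compliance
    of a fusiform aneurysm embedded in the network.  Ships generators for
    laboratory-rig and reduced aortic-chain test networks so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
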