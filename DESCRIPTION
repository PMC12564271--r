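Package: stepwss
Title: Design of Stepped Microfluidic Channels Reproducing Arterial Wall
    Shear Stress Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Design-by-simulation toolkit for variable cross-section
    microfluidic flow chambers that reproduce, in a single channel, both the
    low oscillatory wall shear stress (OWSS) found at the carotid sinus and
    the high pulsatile wall shear stress (PWSS) of healthy arterial segments.
    Provides synthetic cardiac target waveforms, conversion of a target PWSS
    into inlet flow-rate signals via the parallel-plate formula, a
    staggered-grid incompressible Navier-Stokes solver for the stepped
    mid-plane geometry, wall shear stress extraction, streamfunction-based
    vortex characterization, and an RMSE-driven sweep over step dimensions
    that identifies channel geometries meeting a design threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
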