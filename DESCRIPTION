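Package: armstim
Title: Volume-Conductor Simulation of Limb Electrical Stimulation on a
    Layered Digital Arm
Version: 0.1.0
Authors@R:
    person("armstim", "developers", email = "armstim@example.org",
           role = c("aut", "cre"))
Description: Builds a parametric layered digital arm (skin, fat, muscle,
    cortical bone, marrow) as a voxel phantom, renders it into noisy
    grayscale serial sections, segments those sections back into tissues by
    gray-threshold stripping, reconstructs watertight tissue surfaces and a
    conforming label volume, converts the volume into a tagged tetrahedral
    mesh, and solves the quasi-static complex-conductivity potential
    equation for surface-electrode direct and alternating current
    stimulation (tDCS/tACS). Post-processing extracts contact-potential
    traces, current-density line profiles between electrodes, and the
    effective stimulation depth at a current-density threshold. Closed-form
    layered-slab, two-layer annulus, and box-harmonic solutions are
    included as solver verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
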