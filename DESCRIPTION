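Package: sacflow
Title: Pulsatile Casson Blood Flow in Idealized Coiled Sidewall Aneurysms
Version: 0.1.0
Authors@R: person("sacflow", "maintainers", email = "sacflow@example.org", role = c("aut", "cre"))
Description: A desk-scale 2-D computational hemodynamics pipeline for coiled
    cerebral aneurysms. Builds parametric sidewall-aneurysm geometries on a
    curved parent vessel, meshes them on a Cartesian staggered grid, and solves
    transient incompressible Navier-Stokes flow with Casson (shear-thinning,
    haematocrit-dependent) blood rheology, a pulsatile inlet waveform, and a
    Darcy-Forchheimer momentum sink representing endovascular coil packing.
    Post-processing computes wall shear stress, time-averaged WSS, the
    oscillatory shear index, wall pressure, sac inflow velocity and high-risk
    wall regions at the four cardiac-phase landmarks (maximum acceleration,
    peak systole, maximum deceleration, early diastole), and compares them
    across coil porosity and haematocrit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
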