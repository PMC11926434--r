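Package: vheetps
Title: Spot-Scanning Treatment Planning for Very High-Energy Electron Beams
Version: 0.1.0
Authors@R:
    person("Sam", "Ellison", email = "sam.ellison@example.org",
           role = c("aut", "cre"))
Description: Research treatment-planning toolkit for very high-energy
    electron (VHEE, >50 MeV) spot-scanning radiotherapy. Provides an
    analytic beam base-data model (build-up/exponential integrated depth
    dose and Fermi-Eyges multiple-scattering lateral spread), synthetic
    voxel phantoms with structure sets, beam's-eye-view spot placement,
    water-equivalent ray tracing, a pencil-beam influence-matrix dose
    engine, bound-constrained fluence-map optimisation, DVH plan-quality
    metrics, and an automated parameter-sweep pipeline over beam number,
    energy, and spot spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
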