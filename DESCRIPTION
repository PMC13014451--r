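Package: permeakit
Title: Membrane Permeation Analysis from Umbrella-Sampling Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs potentials of mean force from umbrella-sampling
    window trajectories by the weighted histogram analysis method (WHAM)
    with moving-block bootstrap uncertainties, estimates position-dependent
    diffusivity from restrained-window fluctuations, and integrates the
    inhomogeneous solubility-diffusion expressions for membrane permeability
    and resistance. Includes a biased one-dimensional overdamped Langevin
    simulator for generating umbrella windows on configurable free-energy
    and diffusivity landscapes, structural analyses over labeled membrane
    snapshots (contacts, hydration shells, hydrogen bonds, radial
    distribution functions, electron-density profiles), and an MM-GBSA
    style interaction-energy decomposition backed by a minimal nonbonded,
    generalized Born and solvent-accessible surface-area evaluator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
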