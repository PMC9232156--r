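Package: meiosim
Title: Coarse-Grained Langevin Simulation of Meiotic Chromosome Pairing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bead-spring Langevin dynamics of meiotic homologous chromosome
    pairing in budding yeast: chromosomes as excluded-volume polymer chains
    confined to a nuclear sphere, telomeres tethered to the nuclear envelope
    and dragged by motor-driven rapid telomere movements, an optional meiotic
    bouquet bias, and reversible homolog pairing bonds.  Includes in-silico
    strain presets (wild type, csm4, ndj1), the forced-pairing assay that
    detects and classifies topological interlocks (open or closed), planted
    interlock templates with topology-preserving randomization, the
    three-step interlock resolution timeline, primitive path analysis for
    entanglement counting, and ensemble statistics (pairing time courses
    with confidence bands, MSD-based diffusion coefficients, telomere
    velocity profiles, kymographs, binomial proportion intervals and
    two-proportion z-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
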