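Package: toothwave
Title: Reaction-Diffusion Simulation of Sequential Tooth Signaling Center Patterning
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an activator-inhibitor reaction-diffusion model of
    sequential signaling-center patterning in the growing mouse dental
    epithelium. The kinetics switch irreversibly from a bistable to a Turing
    regime as the tissue matures, an oscillatory mesenchymal component primes
    activation at the growing posterior end, and traveling bistable waves can
    erase and re-pattern established Turing peaks (a developmental
    palimpsest). A Keller-Segel-type chemotaxis extension with
    density-dependent inhibitor down-regulation reproduces fusion of adjacent
    signaling centers. Includes linear stability and dispersion analysis,
    kymograph event detection (peak birth, erasure, recovery, fusion, front
    passage with speed), scenario presets, and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'chronogram.R'
    'config.R'
    'domain.R'
    'events.R'
    'fixtures.R'
    'kinetics.R'
    'scenarios.R'
    'solver.R'
    'toothwave-package.R'
    'utils.R'
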