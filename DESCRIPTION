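Package: pairsynapse
Title: Quantal Analysis of Paired Hair-Cell / Afferent-Bouton Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for paired pre- and postsynaptic voltage-clamp
    recordings from cochlear inner hair cells (IHC) and spiral ganglion neuron
    (SGN) boutons. Detects and classifies spontaneous EPSCs, estimates
    spontaneous release rates, fits Boltzmann activation curves to whole-cell
    Ca2+ currents, sigmoidal release-intensity curves, power-law Ca2+
    cooperativity, and exponential-plus-line vesicle-pool depletion from
    forward-masking protocols. Includes a generative simulator of paired
    recordings (Poisson spontaneous release, Boltzmann-gated Ca2+ currents,
    depleting and replenishing vesicle pool) with recorded ground truth so
    that every analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
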