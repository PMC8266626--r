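Package: replitrace
Title: Single-Molecule Fluorescence Analysis of Replisome Helicase Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying helicase loading, stoichiometry, stability
    and transient association at DNA replication forks from two-colour
    single-molecule TIRF data. Provides sub-pixel focus detection and
    intensity extraction, two-colour colocalisation with a chance-coincidence
    model, photobleaching step counting by change-point segmentation,
    Poisson degree-of-labelling calibration, copy-number estimation with
    Gaussian-mixture population fitting, lifetime and FRAP kinetics with
    photobleaching correction, and binding-event statistics. A synthetic-data
    generator emulates intermittently excited EMCCD movies and intensity
    trajectories with known ground truth so that every stage of the pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
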