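Package: ligandMSM
Title: Markov State Model Pipeline for Ligand-Binding Feature Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses Markov state models (MSMs) from molecular
    dynamics feature trajectories of ligand-binding processes. Provides
    time-lagged independent component analysis (TICA), seeded k-means
    discretization with VAMP2 scoring, transition counting and MSM estimation,
    implied timescales, MSM-weighted free-energy landscapes and conditional
    probabilities, transition-path-theory kinetics (committors, reactive flux,
    mean first-passage times), kinetic Monte Carlo trajectory synthesis with
    frame stitching, least-counts adaptive sampling, bootstrap uncertainty
    quantification, and two-ensemble comparison via PCA, symmetrized
    Kullback-Leibler divergence and mutual-information allosteric networks.
    Ships a synthetic trajectory generator with known ground truth so the whole
    pipeline is testable without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
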