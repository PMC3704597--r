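Package: gaitSubspace
Title: Subspace Decomposition of Dichotomous Kinematic Gait Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes dichotomous (two-condition) kinematic marker
    trajectory data into a classifying subspace and its non-classifying
    orthogonal complement. Trials are assembled into a trial-by-variable
    matrix, whitened within subject, and iteratively decomposed by linear
    support-vector-machine discriminants gated by leave-one-subject-out
    binomial classifiability tests; the residual is summarised by principal
    component analysis and the classifying subspace is refined to a single
    discriminant by independent component analysis. Includes stance-phase
    preprocessing of raw trajectories, effect-size ranking of discriminants,
    movement reconstruction in any subspace, and a synthetic-data generator
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    signal,
    nortest,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
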