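Package: popdyn
Title: Population Dynamics Analyses for Goal-Directed Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-area extracellular recordings from a
    free-gaze visual search task: EPSP-kernel spike-density estimation with
    baseline normalization, receptive-field and category/attention unit
    selection, demixed PCA state-space trajectories with shuffle/FDR
    inference, decomposition of population activity into the average
    firing-rate axis and its orthogonal plane, representational geometry
    (distances, vector angles, classifier hyperplane angles,
    Procrustes-aligned subspaces), a 12-indicator lasso encoding model for
    peripheral units, spatial representational similarity analysis, and
    search-efficiency correlates of firing rate and theta-band LFP power.
    Includes a ground-truth synthetic session generator that plants the
    statistical structure every analysis assumes, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
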