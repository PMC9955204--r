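Package: Cas9Dynamics
Title: Markov State Models, tICA and Allosteric Network Analysis of
    Cas9 Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for protein conformational dynamics from
    molecular dynamics trajectories, developed around the CRISPR-Cas9
    HNH/RuvC activation problem. Provides torsion featurization of
    trajectory ensembles, time-lagged independent component analysis
    (tICA) with VAMP2 model selection and feature-contribution
    thresholding, validated Markov state models (Bayesian uncertainty,
    Chapman-Kolmogorov test, PCCA++ macrostate coarse-graining,
    mean first-passage times, reweighted free-energy surfaces),
    macrostate-to-structure association by Jarvis-Patrick clustering,
    residue-coupling allosteric pathway extraction, conformational
    marker distances with Gaussian fits, and nucleic-acid
    pseudorotation / R-loop classification. A synthetic-data module
    generates trajectories with known ground truth so every stage is
    testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
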