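Package: secretomeRules
Title: Rule-Ensemble Classification and Mining of Label-Free Secretome Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying label-free mass-spectrometry secretome
    profiles with stochastic threshold-rule learners and mining the resulting
    rule ensembles for candidate biomarkers. Provides emPAI and peptide-evidence
    probability scoring of protein identifications, assembly of protein-by-sample
    score matrices with an anomalous-sample filter, a seeded evolutionary learner
    producing ordered rule sets with an explicit default class, leave-one-out
    cross-validation with label-permutation significance testing, aggregation of
    thousands of learner runs into per-class protein rankings and protein-pair
    co-prediction networks, and a synthetic-data generator emulating a
    multi-treatment cartilage explant study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    xml2,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Classification, Network
RoxygenNote: 7.3.3
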