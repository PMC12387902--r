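Package: RorschachMap
Title: Unsupervised Association Mapping of Coded Rorschach Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the unsupervised analysis of coded Rorschach protocols
    in small clinical cohorts, developed around the differential picture of
    idiopathic normal pressure hydrocephalus (INPH) versus Alzheimer dementia
    (AD). Provides a SummarizedExperiment-based cohort container with coding
    consistency checks and descriptive statistics, a classical
    multidimensional-scaling projection of subjects with an exhaustive
    linear-separation audit, a 5 x 5 self-organizing map with per-variable
    component planes, an Auto Contractive Map (AutoCM) that learns a
    normalized variable-variable association matrix, and minimum spanning
    tree / maximally regular graph extraction of the association structure,
    together with a calibrated synthetic cohort generator and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
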