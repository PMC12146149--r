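Package: csfcompile
Title: Cross-Study Compilation of Differential Protein Expression in Cerebrospinal Fluid
Version: 0.1.0
Authors@R:
    person("csfcompile", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to harmonize and compile differential-expression results from
    heterogeneous cerebrospinal fluid (CSF) proteomics studies spanning mass
    spectrometry, Olink and SomaScan platforms. Provides protein identifier
    harmonization, recomputation of log2 fold-changes and Benjamini-Hochberg
    adjusted significance from raw abundance matrices, cross-study recurrence
    and UpSet intersection counting, direction-consistency classification,
    fold-change forest compilation with t-based confidence intervals, local
    hypergeometric over-representation analysis against a measured-protein
    background, disease-stage binning of biomarker trajectories, CSF-tissue
    direction concordance, study-level covariate analyses, and a synthetic
    multi-study data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
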