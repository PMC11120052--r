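Package: stagemiR
Title: Stage-Specific miRNA Biomarker Discovery for Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovery and evaluation of stage-specific miRNA biomarkers from
    reads-per-million small-RNA expression cohorts. Implements fold-change
    differential expression with Benjamini-Hochberg adjustment, chi-square
    relevance screening, neighborhood component analysis (NCA) feature
    weighting, minimum-redundancy maximum-relevance (MRMR) ranking by the
    mutual information quotient, per-stage tumor-versus-normal classification
    with stratified five-fold cross-validation, and consensus biomarker
    intersection, together with a synthetic cohort generator with planted
    dysregulation ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
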