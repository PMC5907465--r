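Package: vavalidate
Title: Validation Framework for Verbal Autopsy Cause-Assignment Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating computer-coded verbal autopsy (CCVA)
    algorithms with chance-corrected accuracy metrics. Implements
    chance-corrected concordance (CCC) at the individual level, cause-specific
    mortality fraction (CSMF) accuracy and its chance-corrected form (CCCSMF)
    at the population level, the repeated 75/25 train/test split design with
    Dirichlet resampling of test-set cause composition, empirical estimation
    of cause-conditional symptom endorsement probabilities ("probbase"
    matrices), and deterministic reference classifiers. Includes a synthetic
    gold-standard data generator emulating the structure of multi-site
    validation databases such as the PHMRC gold standard study, so the full
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
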