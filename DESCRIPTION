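Package: ppgbiom
Title: Robust Evaluation of Photoplethysmography-Based Biometric Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and stress-testing photoplethysmography (PPG)
    biometric recognition pipelines. Provides a controllable synthetic
    multi-user, multi-day PPG cohort generator; session windowing and
    resampling utilities; two signal-conditioning chains (cardiac/respiratory/
    blood-volume band decomposition, and detrend-peak-cycle-standardisation
    with multicycle averaging); a 38-value spectral/statistical/MFCC feature
    extractor and a 160-value time/frequency feature extractor over FFT,
    Welch and wavelet components; random-forest and gradient-boosted-tree
    identifiers, a pairwise gradient-boosted re-identifier and a compact 1D
    Siamese convolutional re-identifier; and an evaluation harness with
    multi-class Matthews correlation coefficient, balanced accuracy, random
    baselines, random/temporal/leave-one-out split planners, user-count
    scaling and unseen-user protocols, exact one-sided Wilcoxon signed-rank
    comparisons with Bonferroni correction, and a guideline-adherence report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
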