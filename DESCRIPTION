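Package: eeginfodyn
Title: Information Dynamics of EEG Cortical Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of information storage, information transfer and
    statistically significant directed links in networks of EEG cortical
    sources. Combines Common Spatial Patterns for two-class dimensionality
    reduction, vector autoregressive (VAR) modeling of the reduced
    components, Infomax-type independent component analysis of the VAR
    residuals to resolve instantaneous volume-conduction mixing, and
    computation of linear-Gaussian information dynamics measures from the
    source VAR parameters via the inverse Yule-Walker solution and partial
    variances. Includes a two-condition five-source simulation engine with
    analytic ground truth, preprocessing utilities for scalp EEG, and
    group-comparison statistics (percentage mean absolute deviation,
    Cohen's d with pooled standard deviation, exact Wilcoxon rank-sum).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
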