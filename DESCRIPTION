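Package: serialbias
Title: Serial-Dependence Analysis with Derivative-of-Gaussian Bias Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying serial dependence in continuous-report
    working-memory experiments with circular (180-degree periodic) orientation
    stimuli. Provides circular error arithmetic, outlier exclusion and
    residualization for paired retrocuing / delayed-recall trial tables,
    least-squares fitting of a derivative-of-Gaussian (DoG) bias kernel with a
    signed peak-to-peak effect statistic, permutation tests for the bias and
    for between-condition differences, bootstrap confidence intervals,
    comparison of direct-influence, indirect-influence (two-stage) and null
    models by small-sample-corrected AIC (AICc), bootstrap power analysis, and
    a synthetic experiment generator that reproduces the block and location
    structure of the paired ABC-retrocuing / one-item delayed-recall design so
    the entire pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
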