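Package: pmrwls
Title: Weighted Regression for MethyLight PMR Data with Variable DNA Input
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing percent-of-methylated-reference (PMR)
    measurements from MethyLight assays when the amount of amplifiable input
    DNA varies across specimens.  Provides a binomial fragment-sampling
    simulator of PMR values, empirical variance estimation as a function of a
    DNA-quantity surrogate (by quantile bins or sliding windows), inverse
    variance weighted least squares tests for differential methylation
    between two groups, and a replicate engine for power and type-I-error
    studies across configurable population scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
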