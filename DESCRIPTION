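Package: trizone
Title: Trichotomization of Quantitative Diagnostic Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the score range of a quantitative diagnostic test or
    biomarker into negative, inconclusive and positive decision zones using
    three methods: TG-ROC (two-graph receiver operating characteristics),
    the grey-zone method driven by required post-test probabilities, and the
    uncertain-interval method centred on the intersection of the two class
    densities. Includes the Bayes/likelihood-ratio engine linking pre-test
    probability, sensitivity, specificity and post-test probability;
    evaluation of trichotomized decisions through 3 x 2 tables and
    outer-section metrics; a test-retest simulator for decision reliability;
    and bi-normal synthetic data generators (with Box-Cox normalization)
    for reproducible examples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
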