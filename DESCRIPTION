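Package: reservemr
Title: Two-Sample Mendelian Randomization with Mediation for Brain-Reserve Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) studies of an
    exposure, a family of correlated mediator phenotypes and a binary disease
    outcome, built around the design of education / brain-imaging /
    Alzheimer's-disease analyses. Implements GWAS summary-statistics input and
    output in a fixed tab-delimited dialect, instrument selection, LD clumping,
    proxy lookup and allele harmonization (including the palindromic
    minor-allele-frequency rule), inverse-variance-weighted estimation with
    multiplicative random effects, MR-Egger, weighted-median, contamination
    mixture and MR-PRESSO robust estimators, Cochran's Q, Steiger
    directionality filtering, leave-one-out and funnel diagnostics,
    multivariable MR with difference-in-coefficients mediation decomposition,
    an effective-number-of-tests multiplicity correction derived from a
    phenotypic correlation matrix, analytic power calculations, and a seeded
    synthetic GWAS generator with known causal truth for validating the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
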