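Package: mrmetab
Title: Batch Two-Sample Mendelian Randomization for Blood Metabolite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening large panels of exposures (such as blood
    metabolites) against a disease outcome with two-sample Mendelian
    randomization from GWAS summary statistics. Covers instrument selection
    (p-value threshold, greedy LD clumping, cross-exposure restriction,
    exclusion lists, instrument-count filters), allele harmonization with
    palindromic-SNP resolution, five causal estimators (inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode),
    sensitivity diagnostics (Cochran's Q, Egger intercept, MR-PRESSO global,
    outlier and distortion tests, leave-one-out), a batch driver with a
    multi-model candidate decision rule, and a synthetic two-sample GWAS
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
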