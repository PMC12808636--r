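Package: pwmr
Title: Proteome-Wide Two-Sample Mendelian Randomization with
    Colocalization and Summary-Statistic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of
    circulating protein levels on complex traits such as childhood body
    mass index: GWAS summary-statistic input/output and allele
    harmonization with palindrome handling, cis-pQTL instrument selection
    with F-statistic filtering and LD clumping, Wald ratio, inverse
    variance weighted, MR-Egger, weighted median and weighted mode
    estimators with Benjamini-Hochberg false discovery rate control,
    Bayesian colocalization via Wakefield approximate Bayes factors,
    two-step network MR mediation with the Sobel test, analytic power
    calculations, and a linkage-disequilibrium-aware summary-statistic
    simulator with known causal truth so that every pipeline stage can be
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
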