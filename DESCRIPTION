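Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary
    Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection with p-value, linkage
    disequilibrium (LD) and distance pruning rules, allele harmonization with
    palindromic-variant resolution and LD-proxy substitution, five causal
    estimators (inverse-variance weighted, modified IVW after confounder
    exclusion, maximum likelihood, weighted median, MR-Egger with intercept
    test), instrument-strength and NOME-attenuation diagnostics (mean F and
    I2GX), analytic power calculations for binary and continuous outcomes,
    and a synthetic two-sample GWAS generator with known ground truth for
    calibration and operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
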