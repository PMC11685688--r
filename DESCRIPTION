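Package: mrscan
Title: Two-Sample Mendelian Randomization Scans from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS summary
    statistics: reading and validating summary-statistic tables,
    genome-wide-significance instrument selection, greedy LD clumping with a
    genomic-window rule, outcome-association and cross-trait pleiotropy
    screens, F-statistic instrument-strength evaluation, effect-allele
    harmonization (strand flips and palindromic variants), and causal-effect
    estimation by the Wald ratio and fixed- or multiplicative
    random-effects inverse-variance weighted estimators with odds-ratio
    reporting. Includes a summary-level GWAS simulator with known causal
    effect, within-locus linkage disequilibrium and optional pleiotropy,
    and a batch exposure-by-outcome scan driver with forest-plot data
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
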