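Package: sumgwas
Title: Post-GWAS Inference from Association Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-GWAS inference from association summary
    statistics, organised around a fasting proinsulin meta-analysis
    workflow: per-cohort quality control, double genomic-control
    fixed-effects inverse-variance meta-analysis, locus definition and
    merging, approximate conditional analysis against pluggable linkage
    disequilibrium reference panels with multi-panel consensus,
    approximate-Bayes-factor fine-mapping with LD-extended credible
    sets, pairwise and multi-trait Bayesian colocalization with
    sensitivity scoring and a composite decision rule,
    direction-of-effect classification against companion glycemic
    traits, annotation enrichment with matched control variants, and
    summary-data Mendelian randomization with the HEIDI heterogeneity
    test. A synthetic-data generator produces LD panels, multi-cohort
    GWAS summary statistics, cis-eQTL summary statistics and annotation
    tracks with known truth, so the whole stack is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
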