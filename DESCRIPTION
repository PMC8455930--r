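Package: mtgrs
Title: Multi-Trait Genomic Risk Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of multi-trait genomic risk scores
    (MT-GRS) for a focal disease by re-weighting marginal marker effects
    across genetically correlated traits with a selection index. Includes a
    synthetic multi-trait cohort generator (genotypes in linkage-
    disequilibrium blocks, correlated quantitative and liability-threshold
    binary traits), per-marker marginal association by linear and logistic
    regression, bias-adjusted LD scores, summary-statistic LD-score
    regression for heritability and genetic correlation, clumping-and-
    thresholding marker selection, single-trait and multi-trait genetic
    scoring, incremental Nagelkerke pseudo-R-squared evaluation, percentile
    risk stratification, and a cross-validated pipeline driver with PLINK1
    and delimited-text readers and writers.
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
    withr,
    optparse
Config/testthat/edition: 3
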