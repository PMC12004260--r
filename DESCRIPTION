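Package: prsct
Title: Clumping-and-Thresholding Polygenic Risk Scores with Stratified
    Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-genome polygenic risk scores (PRS) from GWAS
    summary statistics by greedy linkage-disequilibrium clumping and
    p-value thresholding, scores individual-level genotype dosages,
    scans thresholds for the best-fit model, and tests PRS association
    with case-control outcomes in age- and sex-stratified logistic
    models with principal-component adjustment and liability-scale
    variance conversion. Includes sensitivity tools (sentinel-only
    scores, locus exclusion, alternative control sets), regulatory-
    domain gene assignment with hypergeometric gene-set enrichment and
    pathway-restricted PRS, and a liability-threshold simulator of
    LD-blocked genotypes, base GWAS, and ascertained severity cohorts
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
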