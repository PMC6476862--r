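Package: onsetmod
Title: Modifier-Gene Analysis of Alzheimer's Disease Age of Onset in Founder Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-SNP modifier-gene analysis of a quantitative
    age-of-onset trait in related individuals: marker quality control
    (Hardy-Weinberg, call rate, allele count, minor allele frequency),
    maximum-likelihood frequency estimation, genomic-relationship and
    pedigree kinship matrices, kinship-corrected single-locus and stepwise
    multi-locus linear mixed-model association under additive, dominant and
    recessive codings, false-discovery-rate and extreme-value multiple-testing
    correction, full two-locus epistasis decomposition with bootstrap
    confidence intervals and permutation p-values, and Gaussian-mixture
    decomposition of the onset distribution. Includes a pedigree-structured
    synthetic-cohort generator (gene dropping over an endogamous pedigree)
    for calibration, power analysis and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
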