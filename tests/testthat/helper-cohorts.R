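# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

# an empty causal specification (pure-null architecture)
null_spec <- function() {
  data.frame(marker = integer(), coding = character(),
             orientation = character(), beta = numeric(), maf = numeric())
}

# unrelated HWE cohort with hand-controlled marker effects on the phenotype
unrelated_cohort <- function(n = 100, maf = c(0.3, 0.35), beta = c(0, 0),
                             coding = "dominant", sd_e = 4, seed = 1,
                             mu = 48) {
  with_seed(seed, {
    m <- length(maf)
    D <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
    colnames(D) <- paste0("G", seq_len(m))
    sex <- factor(ifelse(runif(n) < 0.5, "female", "male"),
                  levels = c("female", "male"))
    edu <- sample(0:16, n, replace = TRUE)
    grp <- sample(edu_levels(), n, replace = TRUE)
    y <- mu + rnorm(n, 0, sd_e)
    for (j in seq_len(m)) y <- y + beta[j] * code_genotype(D[, j], coding)
    ids <- sprintf("S%03d", seq_len(n))
    list(genotypes = genotype_matrix(D, samples = ids),
         phenotypes = phenotype_table(ids, y, sex, edu, grp),
         K = kinship_matrix(diag(n), ids))
  })
}

# small related null cohort used for calibration-style checks
pedigree_null_config <- function(n = 100, seed = 42) {
  sim_config(n_samples = n, n_markers = 1, causal_spec = null_spec(),
             maf_vector = 0.3, pedigree_depth = 4, founder_count = 14,
             endogamy_rate = 0.5, missing_rate = 0, seed = seed)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
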