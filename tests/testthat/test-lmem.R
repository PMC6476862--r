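test_that("mixed model reduces to OLS when relatedness is absent", {
  co <- unrelated_cohort(n = 80, maf = c(0.3, 0.4), beta = c(3, 0), seed = 2)
  y <- co$phenotypes$adaoo
  X <- cbind(`(Intercept)` = 1, marker = code_genotype(co$genotypes$dosage[, 1],
                                                       "dominant"))
  f0 <- reml_fit(y, X, co$K, sigma_g2 = 0, sigma_e2 = 1)
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(f0$beta), unname(coef(ols)), tolerance = 1e-10)
  # free fit with K = I: coefficients still match OLS (variance split only)
  f1 <- reml_fit(y, X, co$K)
  expect_equal(unname(f1$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_close(f1$sigma_g2 + f1$sigma_e2, sum(resid(ols)^2) / (80 - 2), 1e-6)
})

test_that("coefficients at fixed variance components equal the dense GLS solve", {
  for (s in 1:4) {
    cfg <- sim_config(n_samples = 50, n_markers = 10, seed = s,
                      causal_spec = null_spec(),
                      maf_vector = round(seq(0.1, 0.45, length.out = 10), 2),
                      missing_rate = 0)
    co <- simulate_cohort(cfg)
    y <- co$phenotypes$adaoo
    X <- cbind(1, as.numeric(co$phenotypes$sex == "male"),
               co$phenotypes$edu_years,
               code_genotype(co$genotypes$dosage[, 1 + s], "additive"))
    colnames(X) <- c("(Intercept)", "sexmale", "edu_years", "marker")
    sg <- 6; se <- 11
    fit <- reml_fit(y, X, co$kinship_true, sigma_g2 = sg, sigma_e2 = se)
    V <- sg * unclass(co$kinship_true) + se * diag(length(y))
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_lt(max(abs(fit$beta - drop(b))), 1e-8)
    se_gls <- sqrt(diag(solve(t(X) %*% Vi %*% X)))
    expect_lt(max(abs(fit$se_beta - se_gls)), 1e-8)
  }
})

test_that("REML recovers variance components within tolerance at informative n", {
  res <- vapply(1:12, function(s) {
    cfg <- sim_config(n_samples = 300, n_markers = 2, causal_spec = null_spec(),
                      maf_vector = c(0.3, 0.4), sigma_g2 = 16, sigma_e2 = 9,
                      pedigree_depth = 5, founder_count = 12,
                      endogamy_rate = 0.7, missing_rate = 0, seed = s)
    co <- simulate_cohort(cfg)
    X <- cbind(1, as.numeric(co$phenotypes$sex == "male"),
               co$phenotypes$edu_years)
    f <- reml_fit(co$phenotypes$adaoo, X, co$kinship_true)
    c(f$sigma_g2, f$sigma_e2)
  }, numeric(2))
  expect_close(median(res[1, ]), 16, 0.25 * 16)
  expect_close(median(res[2, ]), 9, 0.25 * 9)
})

test_that("design defects are reported, not silently absorbed", {
  co <- unrelated_cohort(n = 40, maf = 0.3, beta = 0, seed = 1)
  X <- cbind(`(Intercept)` = 1, a = co$phenotypes$edu_years,
             b = 2 * co$phenotypes$edu_years)
  expect_error(reml_fit(co$phenotypes$adaoo, X, co$K), "collinear")
  expect_error(reml_fit(co$phenotypes$adaoo[-1], X, co$K), "aligned")
})

test_that("single-locus scan flags constant markers and orders adjusted p correctly", {
  co <- unrelated_cohort(n = 60, maf = c(0.3, 0.35, 0.4), beta = c(6, 0, 0),
                         seed = 3)
  D <- co$genotypes$dosage
  D[, 3] <- 0  # monomorphic after coding
  g <- genotype_matrix(D, samples = co$genotypes$samples)
  sc <- single_locus_scan(g, co$phenotypes, co$K)
  expect_true(is.na(sc$beta[3]))
  expect_match(sc$reason[3], "constant")
  expect_false(anyNA(sc$beta[1:2]))
  expect_true(all(sc$p_fdr >= sc$p, na.rm = TRUE))
  expect_lt(sc$p[1], 0.01)
  # causal marker recovered with the right sign and magnitude at large n
  co <- unrelated_cohort(n = 800, maf = c(0.2, 0.3), beta = c(8.2, 0), seed = 4)
  sc <- single_locus_scan(co$genotypes, co$phenotypes, co$K)
  expect_close(sc$beta[1], 8.2, 0.8)
  # permuting the phenotype destroys the association
  ph <- co$phenotypes
  ph$adaoo <- with_seed(9, sample(ph$adaoo))
  scp <- single_locus_scan(co$genotypes, ph, co$K)
  expect_gt(min(scp$p_fdr), 0.05)
})

test_that("null scan p-values are uniform", {
  cfg <- pedigree_null_config(n = 100, seed = 21)
  ped <- simulate_pedigree(cfg)
  ek <- eigen_kinship(ped$kinship_true)
  ps <- vapply(1:400, function(r) {
    g <- simulate_genotypes(ped, cfg, seed = r)
    ph <- simulate_phenotype(g, ped$kinship_true, cfg, seed = 50000 + r)
    gd <- code_genotype(g$dosage[, 1], "dominant")
    if (length(unique(gd)) < 2) return(NA_real_)
    X <- cbind(1, as.numeric(ph$sex == "male"), ph$edu_years, marker = gd)
    reml_fit(ph$adaoo, X, eigen_K = ek)$p_values[4]
  }, numeric(1))
  expect_gt(ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  # hand example
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.123), 0.123)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  # brute force: adj_i = min over the upper tail of m * p_j / rank_j
  brute <- function(p) {
    m <- length(p)
    ratio <- vapply(seq_len(m), function(j) m * p[j] / sum(p <= p[j]),
                    numeric(1))
    vapply(seq_len(m), function(i) min(1, ratio[p >= p[i]]), numeric(1))
  }
  with_seed(5, for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), brute(p), tolerance = 1e-12)
  })
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("extreme-value adjustment respects tail ordering and matches empirical p", {
  co <- unrelated_cohort(n = 120, maf = round(runif(20, 0.2, 0.45), 2),
                         beta = c(6, rep(0, 19)), seed = 6)
  ev <- evt_adjust(co$genotypes, co$phenotypes, co$K, n_perm = 400, seed = 2)
  # strong signal above every permutation maximum: deep tail, below 1/B
  j <- which.max(ev$stat_obs)
  expect_gt(ev$stat_obs[j], max(ev$maxima))
  expect_lt(ev$p_evt[j], 1 / 400)
  expect_lte(ev$p_evt[j], ev$p_empirical[j])
  # statistics below every maximum: adjusted p near 1
  low <- which(ev$stat_obs < min(ev$maxima))
  if (length(low)) expect_gt(min(ev$p_evt[low]), 0.9)
  # single-marker panel: fitted tail agrees with the raw permutation p
  ratios <- unlist(lapply(1:10, function(s) {
    co1 <- unrelated_cohort(n = 80, maf = 0.3, beta = 1.5, seed = 100 + s)
    e <- evt_adjust(co1$genotypes, co1$phenotypes, co1$K, n_perm = 500,
                    seed = s)
    if (!e$gev_converged) return(NULL)
    if (e$p_empirical < 0.01 || e$p_empirical > 0.5) return(NULL)
    e$p_evt / e$p_empirical
  }))
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("stepwise selection finds planted signals, guards collinearity, and stays quiet under the null", {
  rec <- data.frame(marker = c(2L, 5L, 9L), coding = "dominant",
                    orientation = "minor", beta = c(8.2, 3.7, 3.3))
  cfg <- sim_config(n_samples = 400, n_markers = 12,
                    maf_vector = round(seq(0.1, 0.45, length.out = 12), 2),
                    causal_spec = rec, sigma_g2 = 2, sigma_e2 = 4,
                    pedigree_depth = 1, founder_count = 400,
                    missing_rate = 0, seed = 31)
  co <- simulate_cohort(cfg)
  ml <- multilocus_select(co$genotypes, co$phenotypes, co$kinship_true,
                          coding = "dominant")
  truth <- co$genotypes$markers$id[rec$marker]
  expect_true(all(truth %in% ml$selected$marker))
  expect_lte(nrow(ml$selected), 5)
  expect_true(all(diff(ml$trace$criterion[ml$trace$action == "add"]) < 0) ||
                nrow(ml$trace) <= 1)
  # duplicated marker: exactly one of the pair enters
  D <- co$genotypes$dosage
  D <- cbind(D, DUP = D[, 2])
  gd <- genotype_matrix(D, samples = co$genotypes$samples)
  ml2 <- multilocus_select(gd, co$phenotypes, co$kinship_true,
                           coding = "dominant")
  expect_equal(sum(ml2$selected$marker %in% c("M002", "DUP")), 1)
  expect_equal(ml2$selected$marker[ml2$selected$marker %in% c("M002", "DUP")],
               "M002")  # earlier input order wins
  # pure-null panels: empty or singleton in most replicates
  sizes <- vapply(1:8, function(s) {
    cfg0 <- sim_config(n_samples = 200, causal_spec = null_spec(),
                       seed = 500 + s)
    co0 <- simulate_cohort(cfg0)
    nrow(multilocus_select(co0$genotypes, co0$phenotypes, co0$kinship_true,
                           coding = "dominant")$selected)
  }, numeric(1))
  expect_gte(mean(sizes <= 1), 7 / 8)
})

test_that("sequential PVE matches its closed form and is bounded", {
  # single causal marker, no covariates: PVE ~ beta^2 Var(code) / Var(y)
  co <- unrelated_cohort(n = 3000, maf = c(0.3, 0.4), beta = c(5, 0), seed = 7)
  y <- co$phenotypes$adaoo
  g1 <- code_genotype(co$genotypes$dosage[, 1], "dominant")
  pv <- onsetmod:::pve_sequential(y, matrix(1, length(y), 1),
                                  cbind(g1, code_genotype(co$genotypes$dosage[, 2],
                                                          "dominant")))
  expect_close(pv$per_marker[1], 25 * var(g1) / var(y), 0.02)
  expect_close(pv$per_marker[2], 0, 0.01)
  expect_true(all(pv$per_marker >= 0))
  expect_lte(pv$total, 1)
  # pve() on a fitted model agrees with the model's own accounting
  cfg <- sim_config(n_samples = 300, seed = 3)
  cs <- simulate_cohort(cfg)
  ml <- multilocus_select(cs$genotypes, cs$phenotypes, cs$kinship_true,
                          coding = "dominant")
  if (nrow(ml$selected)) {
    pv2 <- pve(ml, cs$genotypes, cs$phenotypes)
    expect_equal(unname(pv2$per_marker), ml$selected$pve, tolerance = 1e-10)
    expect_equal(pv2$total, ml$total_pve, tolerance = 1e-10)
  }
})

test_that("heterogeneity LRT is null-calibrated and powered for opposite effects", {
  # same effect in both sexes: no significant specificity expected
  mk_cohort <- function(delta, s) {
    with_seed(s, {
      n <- 600
      d <- rbinom(n, 2, 0.3)
      sex <- factor(ifelse(runif(n) < 0.5, "female", "male"),
                    levels = c("female", "male"))
      eff <- ifelse(sex == "male", 4 + delta, 4)
      y <- 48 + eff * (d > 0) + rnorm(n, 0, 3)
      ids <- sprintf("S%03d", 1:n)
      list(g = genotype_matrix(matrix(d, ncol = 1,
                                      dimnames = list(NULL, "mk")),
                               samples = ids),
           p = phenotype_table(ids, y, sex, sample(0:16, n, TRUE),
                               sample(edu_levels(), n, TRUE)),
           K = kinship_matrix(diag(n), ids))
    })
  }
  co <- mk_cohort(0, 11)
  h0 <- heterogeneity_test("mk", "sex", co$g, co$p, co$K)
  expect_gte(h0$df, 1)
  expect_gt(h0$p, 0.001)
  co <- mk_cohort(-8, 12)
  h1 <- heterogeneity_test("mk", "sex", co$g, co$p, co$K)
  expect_lt(h1$p, 1e-4)
  # mirrors the published table layout: chi2 / df / p columns present
  expect_true(all(c("chi2", "df", "p") %in% names(h1)))
})
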