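test_that("tabular relationship matrix matches hand-derived pedigree values", {
  # unrelated founders: identity
  ped <- data.frame(id = c("a", "b", "c"), sire = NA, dam = NA)
  expect_equal(unclass(kinship_from_pedigree(ped)), diag(3),
               ignore_attr = TRUE)
  # full sibs of non-inbred unrelated parents: relationship 0.5
  ped <- data.frame(id = c("a", "b", "c", "d"),
                    sire = c(NA, NA, "a", "a"), dam = c(NA, NA, "b", "b"))
  A <- kinship_from_pedigree(ped)
  expect_equal(A["c", "d"], 0.5)
  expect_equal(A["c", "c"], 1)
  # offspring of a parent-offspring mating: F = 0.25, diagonal 1.25
  ped <- data.frame(id = c("a", "b", "c"),
                    sire = c(NA, "a", "a"), dam = c(NA, NA, "b"))
  expect_equal(kinship_from_pedigree(ped)["c", "c"], 1.25)
  # ordering contract
  bad <- data.frame(id = c("c", "a", "b"), sire = c("a", NA, NA),
                    dam = c("b", NA, NA))
  expect_error(kinship_from_pedigree(bad), "precede")
})

test_that("simulated pedigrees give identity kinship at depth 1 and PSD kinship always", {
  cfg <- sim_config(n_samples = 20, founder_count = 20, pedigree_depth = 1,
                    causal_spec = null_spec(), n_markers = 4,
                    maf_vector = rep(0.3, 4), seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_equal(unclass(ped$kinship_true), diag(20), ignore_attr = TRUE)
  for (s in 1:5) {
    cfg <- sim_config(n_samples = 50, seed = s, pedigree_depth = 3 + s %% 3,
                      founder_count = 6 + s)
    K <- simulate_pedigree(cfg)$kinship_true
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_true(all(diag(K) >= 1 - 1e-12))
    expect_true(all(K[upper.tri(K)] >= 0))
  }
  expect_error(sim_config(founder_count = 1), "founder_count")
})

test_that("gene dropping preserves allele frequency and respects missingness", {
  cfg <- sim_config(n_samples = 400, n_markers = 6,
                    maf_vector = rep(0.5, 6), causal_spec = null_spec(),
                    pedigree_depth = 1, founder_count = 400,
                    missing_rate = 0, seed = 5)
  g <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  # founders at maf 0.5: pooled frequency within 3 binomial SD
  f <- mean(g$dosage) / 2
  expect_close(f, 0.5, 3 * sqrt(0.25 / (2 * 400 * 6)))
  expect_equal(estimate_frequencies(g)$call_rate, rep(1, 6))
  # no systematic drift across generations in expectation
  cfg2 <- sim_config(n_samples = 150, n_markers = 10,
                     maf_vector = rep(0.3, 10), causal_spec = null_spec(),
                     pedigree_depth = 5, founder_count = 40,
                     missing_rate = 0, seed = 1)
  fr <- vapply(1:20, function(s) {
    cfg2$seed <- s
    class(cfg2) <- "sim_config"
    mean(simulate_genotypes(simulate_pedigree(cfg2), cfg2)$dosage) / 2
  }, numeric(1))
  expect_close(mean(fr), 0.3, 0.03)
  expect_error(sim_config(n_markers = 2, maf_vector = c(0, 0.2),
                          causal_spec = null_spec()), "maf")
})

test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(seed = 17)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$phenotypes$adaoo, c2$phenotypes$adaoo)
  expect_identical(unclass(c1$kinship_true), unclass(c2$kinship_true))
})

test_that("phenotype model reduces to its deterministic and marginal limits", {
  # no genetics, no noise to speak of: all onsets at mu
  cfg <- sim_config(n_samples = 30, n_markers = 2, maf_vector = rep(0.3, 2),
                    causal_spec = null_spec(), sigma_g2 = 0, sigma_e2 = 1e-10,
                    pedigree_depth = 1, founder_count = 30, missing_rate = 0,
                    mu = 47, seed = 2)
  co <- simulate_cohort(cfg)
  expect_close(max(abs(co$phenotypes$adaoo - 47)), 0, 1e-3)
  # one dominant causal SNP at large n: carrier minus non-carrier ~ beta
  cfg <- sim_config(n_samples = 4000, n_markers = 1, maf_vector = 0.3,
                    causal_spec = data.frame(marker = 1L, coding = "dominant",
                                             orientation = "minor", beta = 8.2,
                                             maf = 0.3),
                    sigma_g2 = 0, sigma_e2 = 4, pedigree_depth = 1,
                    founder_count = 4000, missing_rate = 0, seed = 6)
  co <- simulate_cohort(cfg)
  carrier <- co$genotypes$dosage[, 1] > 0
  diff <- mean(co$phenotypes$adaoo[carrier]) - mean(co$phenotypes$adaoo[!carrier])
  expect_close(diff, 8.2, 0.3)
})

test_that("default emulation cohort hits the target onset moments stochastically", {
  ms <- vapply(1:15, function(s) {
    y <- simulate_cohort(sim_config(seed = s))$phenotypes$adaoo
    c(mean(y), sd(y))
  }, numeric(2))
  expect_close(mean(ms[1, ]), 48.8, 0.6)
  expect_close(mean(ms[2, ]), 4.9, 0.6)
  # marginal variance decomposition at large unrelated n
  cfg <- sim_config(n_samples = 4000, n_markers = 1, maf_vector = 0.3,
                    causal_spec = data.frame(marker = 1L, coding = "additive",
                                             orientation = "minor", beta = 2,
                                             maf = 0.3),
                    sigma_g2 = 3, sigma_e2 = 5, pedigree_depth = 1,
                    founder_count = 4000, missing_rate = 0, seed = 9)
  co <- simulate_cohort(cfg)
  expect_close(var(co$phenotypes$adaoo),
               4 * 2 * 0.3 * 0.7 + 3 + 5, 0.8)
})

test_that("fixture suite violates exactly one QC rule per engineered marker", {
  for (s in c(1, 7)) {
    fx <- fixture_suite(s)
    qc_clean <- apply_qc(fx$clean$genotypes)
    expect_equal(sum(qc_clean$report$pass), fx$expected$clean_pass)
    qc_v <- apply_qc(fx$violations$genotypes)
    fails <- qc_v$report[!qc_v$report$pass, ]
    expect_equal(nrow(fails), 5L)
    expect_equal(setNames(fails$reasons, fails$id), fx$expected$reasons)
  }
  # same seed: byte-identical content
  f1 <- fixture_suite(3); f2 <- fixture_suite(3)
  expect_identical(f1$violations$genotypes$dosage, f2$violations$genotypes$dosage)
})

test_that("power estimate equals the level under the null and saturates for huge effects", {
  null_cfg <- sim_config(n_samples = 60, n_markers = 1, maf_vector = 0.3,
                         causal_spec = data.frame(marker = 1L, coding = "dominant",
                                                  orientation = "minor", beta = 0,
                                                  maf = 0.3),
                         pedigree_depth = 1, founder_count = 60,
                         missing_rate = 0, seed = 1)
  pw0 <- power_by_simulation(null_cfg, alpha = 0.05, n_reps = 200, seed = 3)
  expect_true(pw0$ci[1] <= 0.05 && 0.05 <= pw0$ci[2])
  big_cfg <- null_cfg
  big_cfg$causal_spec$beta <- 40
  class(big_cfg) <- "sim_config"
  pw1 <- power_by_simulation(big_cfg, alpha = 0.05, n_reps = 100, seed = 4)
  expect_gte(pw1$power, 0.99)
  expect_error(power_by_simulation(null_cfg, alpha = 1.2, n_reps = 100), "alpha")
})
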