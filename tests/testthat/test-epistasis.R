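# small two-marker cohort with configurable cell-mean surface
two_marker_cohort <- function(n = 300, pa = 0.35, pb = 0.4, seed = 1,
                              surface = function(ga, gb) 0,
                              covar_effect = FALSE, sd_e = 3) {
  with_seed(seed, {
    ga <- rbinom(n, 2, pa); gb <- rbinom(n, 2, pb)
    sex <- factor(ifelse(runif(n) < 0.5, "female", "male"),
                  levels = c("female", "male"))
    edu <- sample(0:16, n, TRUE)
    y <- 48 + surface(ga, gb) + rnorm(n, 0, sd_e)
    if (covar_effect) y <- y + 2 * (sex == "male") + 0.3 * edu
    ids <- sprintf("S%04d", seq_len(n))
    list(g = genotype_matrix(cbind(A = ga, B = gb), samples = ids),
         p = phenotype_table(ids, y, sex, edu, sample(edu_levels(), n, TRUE)))
  })
}

test_that("adjusted cell means reduce to raw means without covariate effects", {
  co <- two_marker_cohort(n = 400, seed = 2,
                          surface = function(ga, gb) 3 * (ga > 0))
  d <- adjusted_cell_means(c("A", "B"), co$g, co$p)
  raw <- adjusted_cell_means(c("A", "B"), co$g, co$p,
                             covariates = character(0))
  occ <- d$cells$n > 0
  expect_equal(d$cells$adj_mean[occ], raw$cells$adj_mean[occ], tolerance = 0.25)
  expect_equal(sum(d$cells$n), d$n_used)
  # covariate effects are removed before comparison
  co2 <- two_marker_cohort(n = 2000, seed = 3, covar_effect = TRUE,
                           surface = function(ga, gb) 0, sd_e = 1)
  d2 <- adjusted_cell_means(c("A", "B"), co2$g, co2$p)
  occ2 <- d2$cells$ok
  expect_lt(diff(range(d2$cells$adj_mean[occ2])), 0.5)
  # monomorphic pair refuses; empty sample overlap refuses
  gm <- genotype_matrix(cbind(A = rep(0, 10), B = rep(2, 10)),
                        samples = sprintf("S%04d", 1:10))
  expect_error(suppressWarnings(adjusted_cell_means(c("A", "B"), gm, co$p)),
               "monomorphic")
  expect_error(adjusted_cell_means(c("A", "B"), gm, co$p[0, ]), "overlapping")
})

test_that("additive surfaces yield null epistatic terms; product surfaces load on aa", {
  co <- two_marker_cohort(n = 6000, seed = 4, sd_e = 1,
                          surface = function(ga, gb) 2 * ga + 1.5 * gb)
  fit <- full_two_locus_fit(adjusted_cell_means(c("A", "B"), co$g, co$p))
  expect_lt(max(abs(fit$estimates[c("aa", "ad", "da", "dd")]), na.rm = TRUE),
            0.25)
  expect_close(fit$estimates[["a1"]], 2, 0.15)
  expect_close(fit$estimates[["a2"]], 1.5, 0.15)
  # planted product interaction recovered
  co2 <- two_marker_cohort(n = 6000, seed = 5, sd_e = 1,
                           surface = function(ga, gb) 1.8 * (ga - 1) * (gb - 1))
  fit2 <- full_two_locus_fit(adjusted_cell_means(c("A", "B"), co2$g, co2$p))
  expect_close(fit2$estimates[["aa"]], 1.8, 0.2)
  expect_lt(fit2$f_epistasis$p, 1e-6)
})

test_that("swapping the marker labels swaps ad with da and fixes aa, dd", {
  co <- two_marker_cohort(n = 1500, seed = 6, sd_e = 2,
                          surface = function(ga, gb)
                            (ga - 1) * (gb == 1) * 2 + 0.7 * (ga == 1) * (gb == 1))
  f_ab <- full_two_locus_fit(adjusted_cell_means(c("A", "B"), co$g, co$p))
  f_ba <- full_two_locus_fit(adjusted_cell_means(c("B", "A"), co$g, co$p))
  expect_close(f_ab$estimates[["aa"]], f_ba$estimates[["aa"]], 1e-8)
  expect_close(f_ab$estimates[["dd"]], f_ba$estimates[["dd"]], 1e-8)
  expect_close(f_ab$estimates[["ad"]], f_ba$estimates[["da"]], 1e-8)
  expect_close(f_ab$estimates[["da"]], f_ba$estimates[["ad"]], 1e-8)
})

test_that("interaction contrasts are valid probabilities with add-one flooring", {
  co <- two_marker_cohort(n = 200, seed = 7,
                          surface = function(ga, gb) 8 * (ga > 0))
  d <- adjusted_cell_means(c("A", "B"), co$g, co$p)
  r <- interaction_contrast(d, list(a_group1 = c(1, 2), a_group2 = 0,
                                    b_stratum = 0:2), B = 300, seed = 1)
  expect_gte(r$p_perm, 1 / 301)
  expect_lte(r$p_perm, 1)
  expect_equal(r$p_perm, 1 / 301)  # planted effect beats every permutation
  expect_true(r$ci_low <= r$delta && r$delta <= r$ci_high)
  expect_close(r$delta, 8, 1.5)
  # identical groups (constant phenotype): p = 1 exactly
  co0 <- two_marker_cohort(n = 300, seed = 8, sd_e = 0,
                           surface = function(ga, gb) 0)
  d0 <- adjusted_cell_means(c("A", "B"), co0$g, co0$p,
                            covariates = character(0))
  r0 <- interaction_contrast(d0, list(a_group1 = c(1, 2), a_group2 = 0,
                                      b_stratum = 0:2), B = 200, seed = 2)
  expect_gt(r0$p_perm, 0.9)
  # inconclusive flag when a contrast group is too small
  tiny <- two_marker_cohort(n = 30, seed = 9, pa = 0.02,
                            surface = function(ga, gb) 0)
  dt <- adjusted_cell_means(c("A", "B"), tiny$g, tiny$p)
  rt <- interaction_contrast(dt, list(a_group1 = 2, a_group2 = 0,
                                      b_stratum = 0), B = 100, seed = 3)
  expect_equal(rt$flag, "inconclusive")
  expect_true(is.na(rt$p_perm))
})

test_that("estimates are invariant to joint sample relabeling and reproducible by seed", {
  co <- two_marker_cohort(n = 250, seed = 10,
                          surface = function(ga, gb) 4 * (ga > 0) * (gb > 0))
  d <- adjusted_cell_means(c("A", "B"), co$g, co$p)
  spec <- list(a_group1 = c(1, 2), a_group2 = 0, b_stratum = 1)
  r1 <- interaction_contrast(d, spec, B = 400, seed = 5)
  r2 <- interaction_contrast(d, spec, B = 400, seed = 5)
  expect_identical(r1, r2)
  # permute all inputs jointly: same estimate
  perm <- with_seed(3, sample(250))
  gp <- genotype_matrix(co$g$dosage[perm, ], samples = co$g$samples[perm])
  pp <- co$p[perm, ]
  dp <- adjusted_cell_means(c("A", "B"), gp, pp)
  rp <- interaction_contrast(dp, spec, B = 400, seed = 5)
  expect_equal(rp$delta, r1$delta, tolerance = 1e-10)
})

test_that("pairwise screen covers C(k,2) pairs and reports partial results", {
  co <- with_seed(11, {
    n <- 250
    D <- cbind(A = rbinom(n, 2, 0.3), B = rbinom(n, 2, 0.4),
               C = rbinom(n, 2, 0.25))
    ids <- sprintf("S%04d", 1:n)
    sex <- factor(ifelse(runif(n) < 0.5, "female", "male"),
                  levels = c("female", "male"))
    y <- 48 + 3 * (D[, 1] > 0) + rnorm(n, 0, 3)
    list(g = genotype_matrix(D, samples = ids),
         p = phenotype_table(ids, y, sex, sample(0:16, n, TRUE),
                             sample(edu_levels(), n, TRUE)))
  })
  scr <- pairwise_screen(c("A", "B", "C"), co$g, co$p, B = 200, seed = 4)
  expect_equal(nrow(scr$pairs), 3)
  expect_true(all(scr$pairs$verdict %in%
                    c("interaction", "no interaction detected")))
  scr2 <- pairwise_screen(c("A", "B", "C"), co$g, co$p, B = 200, seed = 4)
  expect_identical(scr$contrasts, scr2$contrasts)
  # strata without carriers are flagged, the rest still reported
  flags <- scr$contrasts$flag
  expect_true(all(flags %in% c("ok", "inconclusive")))
  expect_gt(sum(flags == "ok"), 0)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    co <- two_marker_cohort(n = n, seed = 12,
                            surface = function(ga, gb) 5 * (ga > 0))
    d <- adjusted_cell_means(c("A", "B"), co$g, co$p)
    r <- interaction_contrast(d, list(a_group1 = c(1, 2), a_group2 = 0,
                                      b_stratum = 0:2), B = 300, seed = 6)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_close(widths[1] / widths[3], 4, 2.1)
})
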