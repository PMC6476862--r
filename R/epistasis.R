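#' Covariate-adjusted genotype-cell means for a marker pair
#'
#' Residualizes the onset phenotype on the covariates by least squares (the
#' grand mean is re-added so cell means stay on the years scale), then
#' tabulates per-cell sample counts and adjusted means over the up-to-3x3
#' genotype combinations of the pair. Samples missing at either marker are
#' dropped. Empty cells and cells below `min_cell_n` are flagged and
#' excluded from contrasts.
#'
#' @param pair length-2 character vector of marker ids.
#' @param genotypes `genotype_matrix` (both markers QC-passed).
#' @param phenotypes `phenotype_table`.
#' @param covariates character vector, as in [single_locus_scan()]; use
#'   `character(0)` for unadjusted means.
#' @param min_cell_n minimum per-cell count for a cell to enter contrasts.
#' @return list of class `two_locus_design`: `pair`, `cells` (ga, gb, n,
#'   adj_mean, ok), `data` (per-sample adjusted y, ga, gb, covariate rows),
#'   `min_cell_n`, `n_used`.
#' @export
adjusted_cell_means <- function(pair, genotypes, phenotypes,
                                covariates = c("sex", "edu_years"),
                                min_cell_n = 3L) {
  stopifnot(length(pair) == 2)
  al <- align_samples(genotypes, phenotypes)
  da <- al$genotypes$dosage[, pair[1]]
  db <- al$genotypes$dosage[, pair[2]]
  keep <- !is.na(da) & !is.na(db)
  if (!any(keep)) stop("no samples with calls at both markers")
  da <- da[keep]; db <- db[keep]
  if (length(unique(da)) < 2 && length(unique(db)) < 2)
    stop("both markers are monomorphic in the analyzed samples")
  y <- al$phenotypes$adaoo[keep]
  ph <- al$phenotypes[keep, , drop = FALSE]
  yadj <- residualize_onset(y, ph, covariates)
  cells <- expand.grid(ga = 0:2, gb = 0:2)
  cells$n <- mapply(function(a, b) sum(da == a & db == b), cells$ga, cells$gb)
  cells$adj_mean <- mapply(function(a, b) {
    idx <- da == a & db == b
    if (any(idx)) mean(yadj[idx]) else NA_real_
  }, cells$ga, cells$gb)
  cells$ok <- cells$n >= min_cell_n
  structure(list(pair = pair, cells = cells,
                 data = list(yadj = yadj, ga = da, gb = db, phen = ph),
                 covariates = covariates,
                 min_cell_n = min_cell_n, n_used = sum(keep)),
            class = "two_locus_design")
}

# OLS residualization of the onset on covariates, grand mean re-added.
residualize_onset <- function(y, phenotypes, covariates) {
  if (!length(covariates)) return(y)
  X <- covariate_design(phenotypes, covariates)
  qr.resid(qr(X), y) + mean(y)
}

#' @export
print.two_locus_design <- function(x, ...) {
  cat(sprintf("two_locus_design %s x %s: n=%d, %d occupied cells\n",
              x$pair[1], x$pair[2], x$n_used, sum(x$cells$n > 0)))
  print(x$cells[x$cells$n > 0, ])
  invisible(x)
}

#' Full two-locus epistatic decomposition
#'
#' Decomposes the covariate-adjusted genotype-mean surface on the
#' Cockerham-style coding: additive scores -1/0/1 (from dosage - 1),
#' dominance scores from heterozygosity, and their four products (aa, ad,
#' da, dd) as epistatic terms. The fit is least squares on the
#' per-sample adjusted phenotype, which equals cell-count-weighted least
#' squares on the cell means; terms the occupied cells cannot identify are
#' dropped and reported as NA. The joint F test of the estimable epistatic
#' terms against the marginal (additive + dominance) model uses the
#' individual-level residual variance, so it remains defined when all nine
#' cells are occupied and the cell-mean surface is saturated.
#'
#' @param design a [adjusted_cell_means()] result.
#' @return list of class `two_locus_fit`: `estimates` (named vector: mu,
#'   a1, d1, a2, d2, aa, ad, da, dd; NA = not estimable), `dropped`,
#'   `f_epistasis` (F, df1, df2, p), `n_cells`.
#' @export
full_two_locus_fit <- function(design) {
  stopifnot(inherits(design, "two_locus_design"))
  ga <- design$data$ga; gb <- design$data$gb
  y <- design$data$yadj
  xa <- ga - 1; da <- as.numeric(ga == 1)
  xb <- gb - 1; db <- as.numeric(gb == 1)
  M <- cbind(mu = 1, a1 = xa, d1 = da, a2 = xb, d2 = db,
             aa = xa * xb, ad = xa * db, da = da * xb, dd = da * db)
  fit_ols <- function(Mx) {
    qrx <- qr(Mx)
    est <- qr.coef(qrx, y)
    list(est = est, rss = sum(qr.resid(qrx, y)^2), rank = qrx$rank)
  }
  full <- fit_ols(M)
  est <- full$est
  dropped <- names(est)[is.na(est)]
  marg <- fit_ols(M[, 1:5, drop = FALSE])
  q <- full$rank - marg$rank
  df2 <- length(y) - full$rank
  f_ep <- if (q > 0 && df2 > 0 && full$rss > 1e-12) {
    Fv <- ((marg$rss - full$rss) / q) / (full$rss / df2)
    list(F = Fv, df1 = q, df2 = df2, p = pf(Fv, q, df2, lower.tail = FALSE))
  } else {
    list(F = NA_real_, df1 = q, df2 = df2, p = NA_real_)
  }
  structure(list(estimates = est, dropped = dropped, f_epistasis = f_ep,
                 n_cells = sum(design$cells$n > 0)),
            class = "two_locus_fit")
}

#' Interaction contrast with bootstrap CI and permutation p
#'
#' Estimates the difference in covariate-adjusted mean onset between two
#' genotype groups of the first marker within a genotype stratum of the
#' second marker (e.g. carrier vs non-carrier of a protective allele among
#' heterozygotes of the partner locus). The confidence interval is a
#' nonparametric percentile bootstrap (samples resampled with replacement
#' from the analysis set, covariate adjustment recomputed per replicate).
#' The p-value is an add-one permutation test: the first marker's genotype
#' labels are permuted against the (partner genotype, covariates, phenotype)
#' tuples, so p = (1 + #\{|D_perm| >= |D_obs|\}) / (B + 1) and is never 0.
#'
#' @param design a [adjusted_cell_means()] result.
#' @param contrast list with `a_group1`, `a_group2` (dosage sets of marker
#'   1, e.g. `c(1, 2)` vs `0`) and `b_stratum` (dosage set of marker 2;
#'   `0:2` for no stratification).
#' @param B bootstrap/permutation replicates (default 10000).
#' @param seed integer seed.
#' @param conf CI level (default 0.95).
#' @return one-row data.frame of class `epistasis_result`: pair, stratum,
#'   contrast label, group sizes, `delta` (years), `ci_low`, `ci_high`,
#'   `p_perm`, `B`, `flag` (`"ok"` or `"inconclusive"`; no p when a group
#'   is below `min_cell_n`).
#' @export
interaction_contrast <- function(design, contrast, B = 10000L, seed = 1L,
                                 conf = 0.95) {
  stopifnot(inherits(design, "two_locus_design"))
  ga <- design$data$ga; gb <- design$data$gb
  yadj <- design$data$yadj
  stratum <- contrast$b_stratum %||% 0:2
  in_str <- gb %in% stratum
  i1 <- in_str & ga %in% contrast$a_group1
  i2 <- in_str & ga %in% contrast$a_group2
  n1 <- sum(i1); n2 <- sum(i2)
  lab <- sprintf("a{%s} vs a{%s} | b{%s}",
                 paste(contrast$a_group1, collapse = ","),
                 paste(contrast$a_group2, collapse = ","),
                 paste(stratum, collapse = ","))
  base <- data.frame(marker_a = design$pair[1], marker_b = design$pair[2],
                     stratum = paste(stratum, collapse = ","),
                     contrast = lab, n_1 = n1, n_2 = n2,
                     delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p_perm = NA_real_, B = as.integer(B), flag = "inconclusive",
                     stringsAsFactors = FALSE)
  class(base) <- c("epistasis_result", "data.frame")
  if (n1 < design$min_cell_n || n2 < design$min_cell_n) return(base)
  delta <- mean(yadj[i1]) - mean(yadj[i2])
  n <- length(yadj)
  ph <- design$data$phen
  boot <- with_seed(substream(seed, 81L), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- residualize_onset(ph$adaoo[idx], ph[idx, , drop = FALSE],
                              design$covariates)
      b1 <- i1[idx]; b2 <- i2[idx]
      if (!any(b1) || !any(b2)) return(NA_real_)
      mean(yb[b1]) - mean(yb[b2])
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE,
                 type = 7)
  # permutation: relabel marker-a genotypes; adjustment is invariant under
  # this relabeling, so only the group means are recomputed
  perm <- with_seed(substream(seed, 82L), {
    vapply(seq_len(B), function(b) {
      gp <- sample(ga)
      j1 <- in_str & gp %in% contrast$a_group1
      j2 <- in_str & gp %in% contrast$a_group2
      if (!any(j1) || !any(j2)) return(NA_real_)
      mean(yadj[j1]) - mean(yadj[j2])
    }, numeric(1))
  })
  nperm_ok <- sum(!is.na(perm))
  p <- (1 + sum(abs(perm) >= abs(delta) - 1e-12, na.rm = TRUE)) / (nperm_ok + 1)
  base$delta <- delta
  base$ci_low <- qs[1]; base$ci_high <- qs[2]
  base$p_perm <- p
  base$flag <- "ok"
  base
}

#' Screen all pairs of selected markers for epistasis
#'
#' Runs [interaction_contrast()] for every unordered pair of the supplied
#' markers with the default contrast family: carrier vs non-carrier of each
#' marker within each genotype stratum of the other. Strata or groups below
#' the minimum cell count are flagged and skipped, the remaining contrasts
#' are still reported. A per-pair verdict (interaction detected or not, at
#' `alpha` on the joint epistasis F test) is attached.
#'
#' @param markers character vector (>= 2) of marker ids, e.g. the
#'   multi-locus model's selected set.
#' @param genotypes,phenotypes,covariates as in [adjusted_cell_means()].
#' @param B replicates per contrast.
#' @param seed integer seed; substreams are derived per pair.
#' @param min_cell_n minimum per-group count.
#' @param alpha verdict level for the joint F test.
#' @return list: `contrasts` (rbind of `epistasis_result` rows), `pairs`
#'   (per-pair F test and verdict), `designs` (named list of
#'   `two_locus_design`).
#' @export
pairwise_screen <- function(markers, genotypes, phenotypes,
                            covariates = c("sex", "edu_years"),
                            B = 10000L, seed = 1L, min_cell_n = 3L,
                            alpha = 0.05) {
  if (length(markers) < 2) stop("need at least 2 markers to screen pairs")
  pairs <- combn(markers, 2, simplify = FALSE)
  out <- list(); pair_rows <- list(); designs <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    des <- adjusted_cell_means(pr, genotypes, phenotypes, covariates,
                               min_cell_n)
    fit <- full_two_locus_fit(des)
    designs[[paste(pr, collapse = "x")]] <- des
    rows <- list()
    ctr <- 0L
    for (flip in c(FALSE, TRUE)) {
      d <- if (!flip) des else {
        des2 <- des
        des2$pair <- rev(des$pair)
        des2$data$ga <- des$data$gb
        des2$data$gb <- des$data$ga
        des2
      }
      for (s in 0:2) {
        if (!any(d$data$gb == s)) next
        ctr <- ctr + 1L
        rows[[length(rows) + 1]] <- interaction_contrast(
          d, list(a_group1 = c(1, 2), a_group2 = 0, b_stratum = s),
          B = B, seed = substream(seed, 200L + 10L * k + ctr))
      }
    }
    rows <- do.call(rbind, rows)
    out[[k]] <- rows
    fp <- fit$f_epistasis$p
    pair_rows[[k]] <- data.frame(
      marker_a = pr[1], marker_b = pr[2],
      f_epistasis = fit$f_epistasis$F, f_p = fp,
      verdict = if (!is.na(fp) && fp < alpha) "interaction"
                else "no interaction detected",
      stringsAsFactors = FALSE)
  }
  list(contrasts = do.call(rbind, out),
       pairs = do.call(rbind, pair_rows),
       designs = designs)
}
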