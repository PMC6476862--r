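#' Maximum-likelihood genotype and allele frequencies
#'
#' With complete biallelic data the ML estimator is the counting estimator:
#' the counted-allele frequency is (2 n_hom + n_het) / (2 n_called) and the
#' genotype frequencies are the observed proportions among called samples.
#' Markers with no calls are flagged and reported as missing, not zero.
#'
#' @param genotypes a `genotype_matrix`.
#' @return data.frame, one row per marker: genotype counts `n0`/`n1`/`n2`,
#'   `n_called`, `call_rate`, counted-allele frequency `freq`, `maf`,
#'   `minor_allele`, `ma_freq_label` (e.g. `"T (0.046)"`), `all_missing`.
#' @export
estimate_frequencies <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosage
  n <- nrow(D)
  n0 <- colSums(D == 0, na.rm = TRUE)
  n1 <- colSums(D == 1, na.rm = TRUE)
  n2 <- colSums(D == 2, na.rm = TRUE)
  n_called <- n0 + n1 + n2
  freq <- ifelse(n_called > 0, (2 * n2 + n1) / (2 * n_called), NA_real_)
  maf <- pmin(freq, 1 - freq)
  mk <- genotypes$markers
  # dosage counts mk$minor_allele (orientation at load); if the realized
  # frequency exceeds 0.5 the sample minor allele is the other one
  counted <- as.character(mk$minor_allele)
  other <- ifelse(counted == as.character(mk$ref), as.character(mk$alt),
                  as.character(mk$ref))
  minor <- ifelse(!is.na(freq) & freq > 0.5, other, counted)
  out <- data.frame(
    id = mk$id,
    n0 = n0, n1 = n1, n2 = n2, n_called = n_called,
    call_rate = n_called / n,
    freq = freq, maf = maf,
    minor_allele = minor,
    ma_freq_label = ifelse(is.na(maf), NA_character_,
                           sprintf("%s (%.3f)", minor, maf)),
    all_missing = n_called == 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of the observed genotype
#' counts against Hardy-Weinberg expectations at the ML allele frequency, or
#' the exact conditional test (probability of the observed heterozygote
#' count given the minor-allele count; two-sided p sums outcomes no more
#' probable than the observed one). Monomorphic markers return p = 1: no
#' departure is testable.
#'
#' @param n0,n1,n2 genotype counts (hom reference-coded, het, hom
#'   counted-allele).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return list with `chi2` (NA for the exact test), `p`, `method`.
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n < 1) stop("hwe_test needs at least one called genotype")
  if (n1 == 0 && (n0 == 0 || n2 == 0)) {
    return(list(chi2 = 0, p = 1, method = method))
  }
  if (method == "chisq") {
    p <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((c(n0, n1, n2) - e)^2 / e)
    list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
         method = method)
  } else {
    # exact test conditional on the minor-allele count
    nA <- 2 * n2 + n1              # counted-allele copies
    if (nA > n) nA <- 2 * n - nA   # het count is symmetric in allele label
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    logp <- vapply(hets, function(h) {
      homA <- (nA - h) / 2
      homB <- n - h - homA
      lfactorial(n) - lfactorial(homA) - lfactorial(h) - lfactorial(homB) +
        h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    }, numeric(1))
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    obs <- match(n1, hets)
    pval <- min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
    list(chi2 = NA_real_, p = pval, method = method)
  }
}

#' Apply marker quality control
#'
#' Removes markers failing any of the four exclusion criteria: (i) deviation
#' from Hardy-Weinberg equilibrium at p < 0.05/m, m being the number of
#' markers entering QC; (ii) call rate below 90%; (iii) a number of alleles
#' other than two; (iv) minor allele frequency below 1%. Thresholds are
#' inclusive on the passing side (call rate exactly 0.90 passes, MAF exactly
#' 0.01 passes, HWE p exactly 0.05/m passes). Every marker is reported with
#' all of its failure reasons; sample order is unchanged. The operation is
#' idempotent.
#'
#' @param genotypes a `genotype_matrix`.
#' @param hwe_alpha HWE exclusion bound; `NULL` (default) uses 0.05/m.
#' @param min_call_rate minimum call rate (default 0.90).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param hwe_method `"chisq"` or `"exact"`.
#' @return list: `genotypes` (filtered), `report` (class `qc_report`:
#'   per-marker call_rate, maf, hwe_p, n_alleles, pass, reasons), and the
#'   thresholds used.
#' @export
apply_qc <- function(genotypes, hwe_alpha = NULL, min_call_rate = 0.90,
                     min_maf = 0.01, hwe_method = "chisq") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  m <- nrow(genotypes$markers)
  hwe_alpha <- hwe_alpha %||% (0.05 / m)
  fr <- estimate_frequencies(genotypes)
  hwe_p <- vapply(seq_len(m), function(j) {
    if (fr$n_called[j] == 0) return(NA_real_)
    hwe_test(fr$n0[j], fr$n1[j], fr$n2[j], hwe_method)$p
  }, numeric(1))
  n_alleles <- genotypes$markers$n_alleles
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  fail_cr <- fr$call_rate < min_call_rate
  fail_allele <- n_alleles != 2L
  fail_maf <- is.na(fr$maf) | fr$maf < min_maf
  reasons <- vapply(seq_len(m), function(j) {
    r <- c(if (fail_hwe[j]) "hwe", if (fail_cr[j]) "call_rate",
           if (fail_allele[j]) "n_alleles", if (fail_maf[j]) "maf")
    paste(r, collapse = ";")
  }, character(1))
  pass <- !(fail_hwe | fail_cr | fail_allele | fail_maf)
  report <- data.frame(id = fr$id, call_rate = fr$call_rate, maf = fr$maf,
                       ma_freq_label = fr$ma_freq_label,
                       hwe_p = hwe_p, n_alleles = n_alleles,
                       pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  attr(report, "thresholds") <- list(hwe_alpha = hwe_alpha,
                                     min_call_rate = min_call_rate,
                                     min_maf = min_maf,
                                     hwe_method = hwe_method,
                                     m_tested = m)
  list(genotypes = subset_genotypes(genotypes, markers = which(pass)),
       report = report,
       thresholds = attr(report, "thresholds"))
}

#' Genomic relationship matrix from genotypes
#'
#' Standardized-genotype estimator K = Z Z' / m, with Z the per-marker
#' dosage centered at 2p and scaled by sqrt(2 p (1-p)) at the ML
#' counted-allele frequency p. Missing dosages are mean-imputed per marker
#' for this computation only. The result is stabilized to positive
#' semidefiniteness by flooring negative eigenvalues at zero. An external
#' pedigree or IBD matrix can be used instead wherever a kinship is
#' accepted.
#'
#' @param genotypes a `genotype_matrix` (QC-passed panel recommended).
#' @param min_markers below this many usable markers a warning about
#'   estimation stability is raised (default 20).
#' @return a `kinship_matrix`.
#' @export
estimate_kinship <- function(genotypes, min_markers = 20L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosage
  fr <- estimate_frequencies(genotypes)
  usable <- which(!fr$all_missing & fr$maf > 0 &
                    genotypes$markers$n_alleles == 2L)
  if (length(usable) < 2) stop("kinship estimation needs >= 2 polymorphic markers")
  if (length(usable) < min_markers) {
    warning(sprintf("only %d usable markers; kinship estimate may be unstable",
                    length(usable)))
  }
  Z <- vapply(usable, function(j) {
    d <- D[, j]
    d[is.na(d)] <- 2 * fr$freq[j]
    (d - 2 * fr$freq[j]) / sqrt(2 * fr$freq[j] * (1 - fr$freq[j]))
  }, numeric(nrow(D)))
  K <- tcrossprod(Z) / length(usable)
  ev <- eigen(K, symmetric = TRUE)
  K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  kinship_matrix(K, genotypes$samples)
}
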