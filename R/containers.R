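#' Genotype matrix container
#'
#' Samples-by-markers minor-allele dosage matrix ({0, 1, 2, NA}) together with
#' per-marker metadata. Dosage counts copies of the minor allele as oriented
#' in the loaded sample; the orientation applied at load time is recorded in
#' the marker table.
#'
#' @param dosage numeric matrix, samples in rows, markers in columns; values
#'   in {0, 1, 2, NA}.
#' @param markers data.frame with one row per marker: columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `n_alleles`, `minor_allele`. Missing
#'   columns are filled with NA / 2.
#' @param samples character vector of unique sample ids (defaults to dosage
#'   rownames).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, markers = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  samples <- samples %||% rownames(dosage) %||% paste0("S", seq_len(nrow(dosage)))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (is.null(markers)) {
    markers <- data.frame(id = colnames(dosage) %||% paste0("M", seq_len(ncol(dosage))))
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!"id" %in% names(markers)) stop("markers table needs an 'id' column")
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (nrow(markers) != ncol(dosage)) stop("markers table does not match dosage columns")
  for (col in c("chrom", "pos", "ref", "alt", "gene", "minor_allele")) {
    if (!col %in% names(markers)) markers[[col]] <- NA
  }
  if (!"n_alleles" %in% names(markers)) markers$n_alleles <- 2L
  bad <- dosage[!is.na(dosage) & !dosage %in% c(0, 1, 2)]
  if (length(bad)) stop("dosage values must be in {0, 1, 2, NA}")
  dimnames(dosage) <- list(samples, markers$id)
  structure(list(dosage = dosage, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param x a `genotype_matrix`.
#' @param samples,markers indices, logical masks or ids; NULL keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$samples) else samples
  if (is.character(si)) si <- match(si, x$samples)
  mi <- if (is.null(markers)) seq_len(nrow(x$markers)) else markers
  if (is.character(mi)) mi <- match(mi, x$markers$id)
  genotype_matrix(x$dosage[si, mi, drop = FALSE],
                  x$markers[mi, , drop = FALSE],
                  x$samples[si])
}

#' Kinship matrix container
#'
#' A symmetric pairwise relatedness matrix used as the covariance structure
#' of the polygenic random effect. Diagonals may exceed 1 under inbreeding.
#'
#' @param values square symmetric numeric matrix.
#' @param samples sample ids (defaults to rownames).
#' @return matrix of class `kinship_matrix` with sample dimnames.
#' @export
kinship_matrix <- function(values, samples = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kinship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("kinship matrix must be symmetric")
  samples <- samples %||% rownames(values) %||% paste0("S", seq_len(nrow(values)))
  values <- (values + t(values)) / 2
  dimnames(values) <- list(samples, samples)
  class(values) <- c("kinship_matrix", "matrix", "array")
  values
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("kinship_matrix: %d samples, mean diag %.3f, mean off-diag %.3f\n",
              nrow(x), mean(diag(x)), if (length(off)) mean(off) else NA_real_))
  invisible(x)
}

#' Phenotype table constructor
#'
#' @param sample_id character ids.
#' @param adaoo age of onset in years (> 0).
#' @param sex factor with levels `female`/`male`.
#' @param edu_years years of education.
#' @param edu_group ordered factor `none` < `elementary` < `high_school` <
#'   `tertiary`.
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_id, adaoo, sex, edu_years, edu_group) {
  if (any(adaoo <= 0)) stop("adaoo must be positive (years)")
  sex <- factor(sex, levels = c("female", "male"))
  edu_group <- factor(edu_group, levels = edu_levels(), ordered = TRUE)
  out <- data.frame(sample_id = as.character(sample_id), adaoo = adaoo,
                    sex = sex, edu_years = edu_years, edu_group = edu_group,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' @export
edu_levels <- function() c("none", "elementary", "high_school", "tertiary")

# Align genotype matrix, phenotype table and kinship on a common sample set.
align_samples <- function(genotypes, phenotypes, K = NULL) {
  ids <- intersect(genotypes$samples, phenotypes$sample_id)
  if (!length(ids)) stop("no overlapping sample ids between genotypes and phenotypes")
  miss_g <- setdiff(phenotypes$sample_id, genotypes$samples)
  miss_p <- setdiff(genotypes$samples, phenotypes$sample_id)
  if (length(miss_g) || length(miss_p)) {
    warning(sprintf("dropping unmatched samples (genotypes only: %d, phenotypes only: %d)",
                    length(miss_p), length(miss_g)))
  }
  g <- subset_genotypes(genotypes, samples = ids)
  p <- phenotypes[match(ids, phenotypes$sample_id), , drop = FALSE]
  if (!is.null(K)) {
    if (!all(ids %in% rownames(K))) stop("kinship matrix is missing samples: ",
                                         paste(setdiff(ids, rownames(K)), collapse = ", "))
    K <- kinship_matrix(unclass(K)[ids, ids, drop = FALSE], ids)
  }
  list(genotypes = g, phenotypes = p, K = K, ids = ids)
}
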