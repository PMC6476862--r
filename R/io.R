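#' Read genotypes from VCF, PLINK text, or wide TSV
#'
#' Loads a biallelic SNV panel as a minor-allele dosage matrix. Alleles are
#' oriented so that dosage counts the allele that is minor *in the loaded
#' sample* (the orientation applied is recorded per marker). Multi-allelic
#' VCF records are passed through with their allele count flagged so the QC
#' allele-number criterion removes them; their dosage is set missing.
#' Coordinates keep the source file's 1-based convention; no liftover.
#'
#' @param path file path (`.vcf`, `.ped` or its `.map` sibling, or a TSV).
#' @param format `"auto"` (by extension), `"vcf"`, `"plink"`, `"tsv"`.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (grepl("\\.(ped|map)$", path)) "plink"
    else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (anyDuplicated(fx$ID)) stop("duplicate marker ids in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  n_alt <- vapply(strsplit(fx$ALT, ","), length, integer(1))
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  dos <- t(dos)  # samples x markers
  dos[, n_alt > 1] <- NA_real_
  markers <- data.frame(id = fx$ID, chrom = fx$CHROM, pos = as.integer(fx$POS),
                        ref = fx$REF, alt = fx$ALT, gene = NA_character_,
                        n_alleles = 1L + n_alt, minor_allele = fx$ALT,
                        stringsAsFactors = FALSE)
  orient_minor(genotype_matrix(dos, markers, colnames(gt)))
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f) || !file.exists(map_f))
    stop("need both ", ped_f, " and ", map_f)
  map <- read.table(map_f, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  if (anyDuplicated(map$id)) stop("duplicate marker ids in .map")
  ped <- read.table(ped_f, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf("malformed .ped: expected %d columns, found %d",
                 6 + 2 * m, ncol(ped)))
  samples <- ped[[2]]
  n <- nrow(ped)
  dos <- matrix(NA_real_, n, m)
  ref <- alt <- character(m)
  n_alleles <- integer(m)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    n_alleles[j] <- length(alleles)
    if (length(alleles) > 2) { ref[j] <- alleles[1]; alt[j] <- alleles[2]; next }
    if (length(alleles) == 0) { ref[j] <- alt[j] <- NA_character_; next }
    cnt <- table(factor(c(a1[a1 != "0"], a2[a2 != "0"]), levels = alleles))
    minor <- alleles[which.min(cnt)]
    major <- if (length(alleles) == 2) alleles[alleles != minor] else minor
    ref[j] <- major; alt[j] <- minor
    miss <- a1 == "0" | a2 == "0"
    dos[, j] <- (a1 == minor) + (a2 == minor)
    dos[miss, j] <- NA_real_
    if (length(alleles) == 1) n_alleles[j] <- 1L
  }
  markers <- data.frame(id = map$id, chrom = as.character(map$chrom),
                        pos = as.integer(map$pos), ref = ref, alt = alt,
                        gene = NA_character_,
                        n_alleles = ifelse(n_alleles == 1, 1L,
                                           pmax(n_alleles, 2L)),
                        minor_allele = alt, stringsAsFactors = FALSE)
  dos[, n_alleles > 2] <- NA_real_
  genotype_matrix(dos, markers, samples)
}

read_genotypes_tsv <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(tb)[1] != "sample_id")
    stop("wide TSV must have 'sample_id' as its first column")
  dos <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  orient_minor(genotype_matrix(dos, samples = tb$sample_id))
}

# Flip dosage columns whose counted-allele frequency exceeds 0.5 so dosage
# counts the sample minor allele; record the flip.
orient_minor <- function(geno) {
  fr <- estimate_frequencies(geno)
  flip <- !is.na(fr$freq) & fr$freq > 0.5
  if (any(flip)) {
    geno$dosage[, flip] <- 2 - geno$dosage[, flip]
    ra <- geno$markers$ref[flip]
    geno$markers$minor_allele[flip] <- ra
  }
  geno$markers$orientation <- ifelse(flip, "flipped_to_minor", "as_loaded")
  geno
}

#' Write genotypes as a plain-text VCF
#'
#' @param genotypes a `genotype_matrix`; dosage is written as unphased GT
#'   with the ALT allele as the counted allele.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  mk <- genotypes$markers
  D <- genotypes$dosage
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(mk)), function(j) {
    g <- D[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    paste(c(as.character(mk$chrom[j]), mk$pos[j], mk$id[j],
            as.character(mk$ref[j]), as.character(mk$alt[j]), ".", "PASS",
            ".", "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes as a wide dosage TSV
#' @param genotypes a `genotype_matrix`.
#' @param path output path; missing dosage is written as `NA`.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  tb <- data.frame(sample_id = genotypes$samples, genotypes$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the phenotype table
#'
#' TSV with header `sample_id adaoo sex edu_years edu_group`.
#' @param path file path.
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "adaoo", "sex", "edu_years", "edu_group")
  if (!all(need %in% names(tb)))
    stop("phenotype TSV must have columns: ", paste(need, collapse = ", "))
  phenotype_table(tb$sample_id, tb$adaoo, tb$sex, tb$edu_years, tb$edu_group)
}

#' @rdname read_phenotypes
#' @param phenotypes a `phenotype_table`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a kinship matrix as a square TSV
#'
#' Square table with sample ids as both header row and first column.
#' @param path file path.
#' @return a `kinship_matrix`.
#' @export
read_kinship <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  kinship_matrix(as.matrix(tb), rownames(tb))
}

#' @rdname read_kinship
#' @param K a `kinship_matrix`.
#' @export
write_kinship <- function(K, path) {
  tb <- data.frame(sample_id = rownames(K), unclass(K), check.names = FALSE)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
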