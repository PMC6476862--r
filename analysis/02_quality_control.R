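#!/usr/bin/env Rscript
# Stage 2: marker QC and relatedness estimation.
#
# Exclusion criteria: HWE p < 0.05/m, call rate < 90%, allele count != 2,
# MAF < 1% (boundaries inclusive on the passing side). Also contrasts the
# genotype-based genomic relationship matrix against the pedigree truth.

suppressPackageStartupMessages(library(onsetmod))
geno <- read_genotypes("results/cohort/genotypes.vcf")
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

qc <- apply_qc(geno)
write.table(as.data.frame(qc$report), "results/qc/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("markers in: %d, passing: %d (HWE bound %.2e)\n",
            nrow(qc$report), sum(qc$report$pass), qc$thresholds$hwe_alpha))
fails <- qc$report[!qc$report$pass, ]
if (nrow(fails)) {
  cat("removed:\n")
  print(fails[, c("id", "call_rate", "maf", "hwe_p", "reasons")])
} else cat("no markers removed\n")

grm <- estimate_kinship(qc$genotypes)
write_kinship(grm, "results/qc/kinship_grm.tsv")
Kp <- read_kinship("results/cohort/kinship_pedigree.tsv")
r <- cor(grm[upper.tri(grm)], unclass(Kp)[upper.tri(Kp)])
cat(sprintf("GRM vs pedigree kinship: off-diagonal correlation %.2f\n", r))
cat(sprintf("(the LMEM accepts either; the pipeline default uses the pedigree matrix when present)\n"))
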