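#' Pipeline configuration
#'
#' Validated configuration for the end-to-end analysis: simulate (or load)
#' genotypes, phenotypes and kinship; QC the panel; run the single-locus
#' scan; build the multi-locus model; screen selected pairs for epistasis;
#' and decompose the onset distribution. Unknown arguments are rejected.
#'
#' @param sim a [sim_config()] for synthetic mode, or NULL to load files.
#' @param genotype_file,phenotype_file,kinship_file input paths for loaded
#'   mode (`kinship_file` optional; the genomic relationship matrix is
#'   estimated when absent).
#' @param genotype_format passed to [read_genotypes()].
#' @param kinship_source `"auto"` (pedigree truth in synthetic mode, else
#'   GRM), `"grm"`, `"pedigree"`, or `"file"`.
#' @param hwe_alpha,min_call_rate,min_maf,hwe_method QC thresholds
#'   ([apply_qc()]).
#' @param coding,orientation,covariates model settings.
#' @param max_steps,criterion,gamma multi-locus selection settings.
#' @param n_perm permutations for the extreme-value scan correction.
#' @param B bootstrap/permutation replicates for epistasis contrasts.
#' @param alpha nominal test level.
#' @param mixture_ks candidate mixture component counts.
#' @param onset_cutoff early/late dichotomization age (years).
#' @param seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            genotype_file = NULL, phenotype_file = NULL,
                            kinship_file = NULL, genotype_format = "auto",
                            kinship_source = c("auto", "grm", "pedigree", "file"),
                            hwe_alpha = NULL, min_call_rate = 0.90,
                            min_maf = 0.01, hwe_method = "chisq",
                            coding = "dominant", orientation = "minor",
                            covariates = c("sex", "edu_years"),
                            max_steps = 10L, criterion = "ebic", gamma = 0.5,
                            n_perm = 1000L, B = 10000L, alpha = 0.05,
                            mixture_ks = 1:3, onset_cutoff = 48,
                            seed = 1L) {
  kinship_source <- match.arg(kinship_source)
  if (is.null(sim) && (is.null(genotype_file) || is.null(phenotype_file)))
    stop("either a sim config or genotype_file + phenotype_file is required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> QC -> single-locus scan -> multi-locus
#' selection -> pairwise epistasis -> onset-distribution decomposition, in
#' order. When `out_dir` is given every intermediate is persisted as
#' TSV/JSON plus a Markdown summary; the persisted artifacts are a pure
#' function of (inputs, config, seed), so identical runs are byte-identical
#' (stage wall-clock times are returned in the R object but never written).
#' A stage failure stops the run with prior outputs intact.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL for no files.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  persist <- function(obj, file, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }
  tsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  json <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE,
                                                 na = "null")

  # stage 1: inputs
  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      co <- simulate_cohort(config$sim)
      list(genotypes = co$genotypes, phenotypes = co$phenotypes,
           kinship_pedigree = co$kinship_true, pedigree = co$pedigree,
           truth = co$truth)
    } else {
      geno <- read_genotypes(config$genotype_file, config$genotype_format)
      phen <- read_phenotypes(config$phenotype_file)
      bad <- symdiff_ids(geno$samples, phen$sample_id)
      if (length(bad$only_geno) || length(bad$only_phen))
        stop("sample ids do not match between genotype and phenotype files; ",
             "genotypes only: [", paste(bad$only_geno, collapse = ", "),
             "], phenotypes only: [", paste(bad$only_phen, collapse = ", "), "]")
      kin <- if (!is.null(config$kinship_file)) read_kinship(config$kinship_file)
      list(genotypes = geno, phenotypes = phen, kinship_pedigree = kin)
    }
  })
  persist(inputs$phenotypes, "phenotypes.tsv", write_phenotypes)
  persist(inputs$genotypes, "genotypes.tsv", write_genotypes_tsv)

  # stage 2: QC
  qc <- stage("qc", apply_qc(inputs$genotypes, hwe_alpha = config$hwe_alpha,
                             min_call_rate = config$min_call_rate,
                             min_maf = config$min_maf,
                             hwe_method = config$hwe_method))
  persist(as.data.frame(qc$report), "qc_report.tsv", tsv)
  persist(c(qc$thresholds,
            list(n_markers_in = nrow(qc$report),
                 n_markers_pass = sum(qc$report$pass))),
          "qc_summary.json", json)
  if (!any(qc$report$pass)) {
    stop("no markers survived QC; report persisted, downstream stages skipped")
  }

  # kinship
  K <- stage("kinship", {
    src <- config$kinship_source
    if (src == "auto") src <- if (!is.null(inputs$kinship_pedigree)) "pedigree"
                              else "grm"
    switch(src,
           pedigree = inputs$kinship_pedigree,
           file = inputs$kinship_pedigree,
           grm = estimate_kinship(qc$genotypes))
  })
  persist(K, "kinship.tsv", write_kinship)

  # stage 3: single-locus scan
  scan <- stage("scan", single_locus_scan(
    qc$genotypes, inputs$phenotypes, K, coding = config$coding,
    orientation = config$orientation, covariates = config$covariates,
    n_perm = config$n_perm, seed = substream(config$seed, 31L)))
  persist(as.data.frame(scan), "scan.tsv", tsv)

  # stage 4: multi-locus model
  ml <- stage("multilocus", multilocus_select(
    qc$genotypes, inputs$phenotypes, K, coding = config$coding,
    orientation = config$orientation, covariates = config$covariates,
    max_steps = config$max_steps, criterion = config$criterion,
    gamma = config$gamma))
  persist(list(selected = ml$selected, total_pve = ml$total_pve,
               sigma_g2 = ml$sigma_g2, sigma_e2 = ml$sigma_e2,
               pseudo_h2 = ml$pseudo_h2, criterion = ml$criterion,
               trace = ml$trace), "multilocus.json", json)

  # stage 5: epistasis on the selected set
  epi <- stage("epistasis", {
    if (nrow(ml$selected) >= 2) {
      pairwise_screen(ml$selected$marker, qc$genotypes, inputs$phenotypes,
                      covariates = config$covariates, B = config$B,
                      seed = substream(config$seed, 41L),
                      alpha = config$alpha)
    }
  })
  if (!is.null(epi)) {
    persist(epi$contrasts, "epistasis_contrasts.tsv", tsv)
    persist(epi$pairs, "epistasis_pairs.tsv", tsv)
  }

  # stage 6: onset distribution
  pheno <- stage("phenostats", {
    y <- inputs$phenotypes$adaoo
    mix <- select_mixture(y, ks = config$mixture_ks,
                          seed = substream(config$seed, 51L))
    dich <- dichotomize_onset(y, config$onset_cutoff)
    tests <- rbind(group_tests(inputs$phenotypes, "sex"),
                   group_tests(inputs$phenotypes, "edu_group"),
                   group_tests(inputs$phenotypes, "edu_years"))
    tests$design <- c("sex", "edu_group", "edu_years")
    list(mixture = mix, dichotomy = dich, tests = tests)
  })
  persist(list(best_k = pheno$mixture$best_k, bic = as.list(pheno$mixture$bic),
               weights = pheno$mixture$best$weights,
               means = pheno$mixture$best$means,
               sds = pheno$mixture$best$sds,
               loglik = pheno$mixture$best$loglik),
          "mixture.json", json)
  persist(pheno$tests, "group_tests.tsv", tsv)

  report <- structure(list(
    package_version = as.character(utils::packageVersion("onsetmod")),
    config = config, seed = config$seed,
    n_samples = length(inputs$genotypes$samples),
    n_markers_in = nrow(qc$report),
    n_markers_pass = sum(qc$report$pass),
    qc = qc$report, kinship = K, scan = scan, multilocus = ml,
    epistasis = epi, phenostats = pheno,
    timings = timings), class = "run_report")
  if (!is.null(out_dir)) {
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  report
}

symdiff_ids <- function(a, b) {
  list(only_geno = setdiff(a, b), only_phen = setdiff(b, a))
}

#' Render a run report as Markdown
#'
#' Deterministic given the report's analytic content: timings and other
#' run-environment details are deliberately excluded so reruns with the
#' same config and seed are byte-identical.
#'
#' @param report a `run_report`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  ml <- report$multilocus
  lines <- c(
    "# Onset modifier analysis report",
    "",
    sprintf("- samples: %d; markers in: %d; markers passing QC: %d",
            report$n_samples, report$n_markers_in, report$n_markers_pass),
    sprintf("- seed: %d; coding: %s; covariates: %s", report$seed,
            report$config$coding, paste(report$config$covariates,
                                        collapse = ", ")),
    "",
    "## QC failures", "")
  fails <- report$qc[!report$qc$pass, , drop = FALSE]
  lines <- c(lines, if (nrow(fails)) {
    sprintf("- %s: %s", fails$id, fails$reasons)
  } else "- none")
  top <- report$scan[order(report$scan$p), ][seq_len(min(5, nrow(report$scan))), ]
  lines <- c(lines, "", "## Single-locus scan (top markers)", "",
             "| marker | beta (years) | SE | p | p_FDR |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %s |", top$id, fmt(top$beta),
                     fmt(top$se), fmt(top$p), fmt(top$p_fdr)))
  lines <- c(lines, "", "## Multi-locus model", "",
             sprintf("- selected markers: %d (criterion %s)",
                     nrow(ml$selected), ml$criterion$name),
             sprintf("- total variance explained: %s", fmt(ml$total_pve)),
             sprintf("- pseudo-heritability: %s", fmt(ml$pseudo_h2)))
  if (nrow(ml$selected)) {
    lines <- c(lines, "",
               "| marker | beta | SE | p | PVE |", "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |", ml$selected$marker,
                       fmt(ml$selected$beta), fmt(ml$selected$se),
                       fmt(ml$selected$p), fmt(ml$selected$pve)))
  }
  if (!is.null(report$epistasis)) {
    lines <- c(lines, "", "## Epistasis screen", "",
               sprintf("- %s x %s: %s (F p = %s)",
                       report$epistasis$pairs$marker_a,
                       report$epistasis$pairs$marker_b,
                       report$epistasis$pairs$verdict,
                       fmt(report$epistasis$pairs$f_p)))
  }
  mix <- report$phenostats$mixture
  lines <- c(lines, "", "## Onset distribution", "",
             sprintf("- mixture: best k = %d (BIC); means = %s years",
                     mix$best_k, paste(fmt(mix$best$means), collapse = ", ")),
             sprintf("- early/late at %s years: %d early, %d late",
                     fmt(report$phenostats$dichotomy$cutoff),
                     report$phenostats$dichotomy$summary$n[1],
                     report$phenostats$dichotomy$summary$n[2]))
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
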