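# onsetmod

Modifier-gene analysis of Alzheimer's disease age of onset (ADAOO) in
founder pedigrees.

In kindreds segregating a fully penetrant early-onset mutation (the
motivating setting is a PSEN1 E280A founder pedigree), every carrier
develops the disease but onset age spreads over decades. `onsetmod`
implements the statistical pipeline for finding the variants that shift
onset: marker QC, kinship-corrected association, multi-locus model
building, two-locus epistasis, and decomposition of the onset
distribution — together with a pedigree-structured synthetic-cohort
generator that reproduces the statistical structure such a study assumes,
so every stage can be calibrated and tested end to end.

## The model

Association inference uses the linear mixed model

    y = Xb + u + e,   u ~ N(0, sg2 * K),   e ~ N(0, se2 * I)

with `y` the onset in years, `X` an intercept, sex, years of education and
coded marker terms (additive {0,1,2}, dominant {0,1,1} or recessive
{0,0,1} on minor-allele dosage, with an orientation flip), and `K` a
kinship matrix — pedigree-derived (tabular method), a genomic relationship
matrix, or loaded from file. REML estimation profiles the single variance
ratio after one spectral decomposition of `K` (exact for one random
effect). On top of that sit: BH-FDR and extreme-value (permutation + GEV)
multiple-testing correction; forward/backward multi-locus selection under
an extended-BIC criterion with sequential variance-explained accounting;
a full two-locus epistatic decomposition (a1, d1, a2, d2, aa, ad, da, dd)
of covariate-adjusted genotype-cell means with percentile-bootstrap CIs
and add-one permutation p-values; and a Gaussian-mixture EM for the onset
distribution with BIC component choice.

## Worked example

```r
library(onsetmod)

# a synthetic cohort under the default study conditions:
# 78 related carriers, 65 markers, 3 causal modifier loci
co <- simulate_cohort(sim_config(seed = 42))
co
#> synthetic_cohort: n=78, m=65, ADAOO mean 49.4 sd 5.0

qc <- apply_qc(co$genotypes)
sum(qc$report$pass)
#> [1] 65

scan <- single_locus_scan(qc$genotypes, co$phenotypes, co$kinship_true,
                          coding = "dominant")
head(scan[order(scan$p), c("id", "beta", "se", "p", "p_fdr")], 3)
#>      id      beta        se            p       p_fdr
#> 23 M023  4.328261 0.9944314 4.369603e-05 0.002840242
#> 5  M005  6.887913 2.1207825 1.758457e-03 0.057149847
#> 54 M054 -2.992209 1.1056902 8.468018e-03 0.166087001

ml <- multilocus_select(qc$genotypes, co$phenotypes, co$kinship_true,
                        coding = "dominant")
ml
#> multilocus_model (dominant, ebic): 3 markers, total PVE 0.397, pseudo-h2 0.136
#>   marker order   coding     beta        se            p       pve
#> 1   M023     1 dominant 4.285952 0.8714063 5.328698e-06 0.1964038
#> 2   M005     2 dominant 7.477279 1.8103079 9.637534e-05 0.1060473
#> 3   M050     3 dominant 3.696114 1.0844523 1.073869e-03 0.0950330
```

The true modifier loci in this cohort are M005 (+8.2 years, dominant,
MAF 0.046), M023 (+3.7, dominant) and M041 (+3.3, recessive on the minor
allele). The dominant-coded model recovers both dominant effects with
estimates covering the truth (7.5 ± 1.8 and 4.3 ± 0.9 years), misses the
recessive locus under this coding — rerunning with `coding = "recessive"`
is exactly what the three-coding scan is for — and admits one false
selection, realistic behavior at n = 78. The joint model explains ~40% of
the onset variance. At n = 400 the same pipeline recovers all three
planted effects in >= 80% of replicates (see the test suite and
`analysis/07_power_and_calibration.R`).

The full workflow — cohort, QC, scan, multi-locus model, epistasis screen,
onset decomposition, power/calibration — is scripted as numbered drivers:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_quality_control.R
...
Rscript analysis/07_power_and_calibration.R
```

each writing its tables under `results/`. `run_pipeline(pipeline_config())`
runs the same stages in one call and persists a Markdown + JSON report
that is byte-identical across reruns with the same config and seed.

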