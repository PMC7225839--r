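# znblup

Genomic prediction of maize kernel zinc concentration with RR-BLUP/GBLUP.

Kernel zinc (Zn) biofortification is a breeding target for maize-staple
regions where Zn deficiency is widespread (the HarvestPlus target is 33
mg/kg, against typical panel means near 26 mg/kg). Phenotyping kernel Zn is
slow and expensive, which makes genomic selection (GS) attractive: train a
whole-genome marker model on a phenotyped population, then select on
genomic estimated breeding values (GEBVs) alone. `znblup` is a toolkit for
exactly that workflow — and for the design questions that come with it: how
many training lines, how many markers, how much marker quality, which lines
to phenotype, whether cheap dominant presence/absence markers (rAmpSeq-style
tags) can replace GBS SNPs, and whether a handful of associated markers
(marker-assisted selection, MAS) competes with whole-genome prediction.

## The model

The core is the standard ridge-regression BLUP mixed model

    y = 1 mu + Z u + e,    u ~ N(0, I sigma_u^2),   e ~ N(0, I sigma_e^2)

with `Z` the (training-frequency-)centered n x m dosage matrix, dual to
GBLUP with the VanRaden method-1 genomic relationship matrix
`K = W W' / c`, `c = sum 2 p (1 - p)`. Variance components are estimated by
REML, profiled down to the single ratio `delta = sigma_e^2 / sigma_A^2`
through one spectral decomposition (EMMA construction) and maximized by
Brent search; the marker-scale ridge parameter is `lambda = c * delta`, so
the two parameterizations agree exactly. Narrow-sense heritability is
`h2 = V_A / (V_A + V_e)` with `V_A` on the population scale
(`mean(diag(K))` times the K-scale coefficient — the distinction matters
for inbred material, where the GRM diagonal averages ~2).

Around the core: genotype QC (MAF and missing-rate filters for codominant
and dominant platforms), mean imputation, HapMap/VCF/CSV readers,
least-squares genotype means across environments, and the full evaluation
battery (replicated k-fold CV, training-size/marker-density/marker-quality
sweeps, phenotype-stratified training sets, cross-population transfer, MAS
comparison, Welch tests). A synthetic-data module simulates diverse inbred
panels (U-shaped allele-frequency spectra, optional LD blocks, dispersed
GBS-like missingness) and doubled-haploid crosses (Haldane crossovers on a
10-chromosome map) with additive architectures calibrated to a target
heritability, so the whole pipeline runs with no external data.

## Worked example

```r
library(znblup)

cfg <- sim_config(pop_type = "panel", n_ind = 236, markers_per_chrom = 100,
                  n_qtl = 40, h2_target = 0.84, seed = 7)
geno <- simulate_panel(cfg)                     # 236 x 1000 inbred dosages
sim  <- simulate_phenotypes(geno, cfg)          # 3 locations, Zn-like scale
ls   <- ls_means(sim$records)                   # adjusted genotype means

fit <- rrblup(ls$lsmean, geno)                  # REML ridge + GEBVs
fit
#> rrblup fit: 236 lines, 1000 markers (lambda = 98.67)
#>   REML: V_A = 8.5141, V_e = 2.3311, h2 = 0.785
#>   intercept (GLS mean) = 26.6943

kfold_cv(ls$lsmean, geno, k = 5, n_reps = 20, seed = 1)
#> cv_result: 20 replicate(s), mean accuracy 0.399 (sd 0.035, se 0.008)
#>   k=5 n_reps=20 seed=1 n=236 m=1000
```

The REML heritability (0.79) recovers the simulation target (0.84) to
within its sampling noise, and the fivefold cross-validation accuracy
(0.40) is the mean over 20 replicate
partitions of the correlation between predicted and observed lsmeans in the
held-out folds — the quantity a breeder would use to size a GS program.
`predict(fit, new_geno)` scores new lines; `summary()`, `coef()`,
`residuals()`, `plot()` and `simulate()` behave as for any fitted R model.

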