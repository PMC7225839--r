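---
title: "Genomic prediction of maize kernel zinc: models, simulations and design choices"
author: "znblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of maize kernel zinc: models, simulations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znblup)
```

`znblup` implements a complete genomic-selection (GS) analysis stack for a
quantitative kernel trait — kernel zinc concentration in maize is the
motivating case — from raw genotype calls to the design experiments a
breeding program runs before committing to GS. This vignette is the
package's own account of the science: the models, the simulation engine
that stands in for field data, and the numerical and design decisions that
were genuinely open.

## 1. The prediction model

The workhorse is ridge-regression BLUP (RR-BLUP). For $n$ lines and $m$
markers,

$$ y = \mathbf{1}\mu + Z u + \varepsilon, \qquad
   u \sim N(0, I\sigma_u^2), \quad \varepsilon \sim N(0, I\sigma_e^2), $$

where $y$ holds one adjusted phenotype per line (the least-squares genotype
mean across environments) and $Z$ is the dosage matrix centered by the
*training set's* allele frequencies. This is exactly dual to GBLUP with the
VanRaden method-1 genomic relationship matrix (GRM)

$$ K = \frac{WW'}{c}, \qquad c = \sum_j 2 p_j (1 - p_j), $$

($p_j$ = observed allele frequency; for dominant presence/absence markers
the centering is by the presence frequency and $c = \sum_j p_j(1-p_j)$).
`rrblup()` solves the ridge equations through the equivalent $n \times n$
system, so cost scales with population size (hundreds) rather than marker
count (up to hundreds of thousands), and `predict()` enforces the
training-frequency centering contract on new genotypes. The duality is a
tested invariant: fitted genetic values equal $K(K + \delta I)^{-1}(y -
\hat\mu)$ to $10^{-8}$ on every instance tried.

### REML variance components

With only an intercept as fixed effect, the restricted likelihood profiles
down to the variance ratio $\delta = \sigma_e^2/\sigma_A^2$. We decompose
$S(K + I)S$ (with $S$ the centering projector) once and maximize the
profiled restricted log-likelihood over $\log\delta \in [-10, 10]$ by Brent
search (tolerance $10^{-8}$), guarding both interval ends. Decomposing
$S(K+I)S$ rather than $SKS$ matters: when $K$ is rank-deficient ($m < n$)
the null space of $SKS$ mixes the intercept direction with genuine null
directions of $K$, and the likelihood silently degrades; the $+I$ shift
pins the intercept direction at eigenvalue 0 and every other direction at
$\xi_i + 1 > 0$. The optimum is verified in the test suite against an
independently coded `solve()`-based restricted likelihood on a 2,001-point
grid.

**Heritability scale.** An individual's additive variance under GBLUP is
$K_{ii}\sigma_K^2$, and for fully inbred material (DH lines, inbred panels)
the VanRaden diagonal averages $1 + F \approx 2$. The package therefore
reports $V_A = \overline{\mathrm{diag}(K)}\,\sigma_K^2$ — the additive
variance on the phenotypic scale — so that $h^2 = V_A/(V_A + V_e)$ is the
true variance ratio. Reporting the raw coefficient $\sigma_K^2$ instead
would understate inbred-panel $h^2$ by ~0.13 at $h^2 \approx 0.75$. The
ridge conversion uses the coefficient scale: $\lambda = c\,\delta$.

### Phenotype adjustment

`ls_means()` fits `value ~ genotype + environment` by fixed-effects least
squares with sum-to-zero environment contrasts and reports each genotype at
the average environment. Environment is arguably a random effect, but for
genotype means the fixed fit gives identical rankings in balanced designs
and a transparent estimable-function check (the genotype-by-environment
incidence graph must be connected) in unbalanced ones; lattice/incomplete
block adjustments are out of scope. Replicates are averaged within
genotype-by-environment cells first. The unbalanced case is tested against
`emmeans` to $10^{-10}$.

## 2. The synthetic populations

Real multi-environment Zn trials and GBS genotypes are large and external;
the package ships a generator whose **defaults are the study conditions**,
so every experiment runs at desk scale.

* **Diverse inbred panel** (`simulate_panel()`): fully homozygous lines
  ($\{0,2\}$ dosages); each marker's allele frequency drawn from
  Beta(0.3, 0.3), a U-shaped spectrum in which most markers are rare —
  matching diverse tropical GBS panels where ~65% of raw markers have
  MAF < 0.05. Loci are independent by default. An optional
  *block-haplotype* mode (`ld_block_size`, `n_founder_haplotypes`) draws
  consecutive markers within a block from a small founder-haplotype pool,
  giving within-block linkage disequilibrium; it exists because the
  marker-density experiment is scientifically about tagging QTL through
  LD, which independent loci cannot express.
* **DH populations** (`simulate_dh()`): each line is one doubled F1 gamete
  from two inbred parents on a 10-chromosome map (default 150 cM each).
  Crossover counts are Poisson(map length / 100) with uniform positions —
  the Haldane no-interference model, the simplest standard choice.
  Consequences that the tests assert: lines are fully homozygous, carry
  only parental alleles, and segregating markers sit at frequency 1/2.
* **Dominant platform** (`to_dominant()`): per marker one allele is
  designated tag-present; carriers score 1, non-carriers 0. On complete
  homozygous data this is information-preserving up to labeling
  (`expand_dominant()` inverts it — a tested round trip). The platform's
  real information loss is *dropout conflation*: a presence/absence assay
  cannot distinguish a failed amplification from true absence, so missing
  input calls score 0 by default. This single mechanism reproduces the
  empirical platform hierarchy (SNPs beat tags at equal marker content
  under realistic missingness) and explains why dominant data admit a MAF
  filter but no missing-rate filter.
* **Missingness** (`inject_missing()`, `sim_missing_profile()`): the
  scalar form masks cells iid at a given rate. Real GBS missingness is
  strongly dispersed across markers, so the profile form draws per-marker
  rates from Beta$(\bar r c, (1-\bar r)c)$ with mean $\bar r = 0.29$ (the
  pre-filter average this package emulates) and concentration $c = 1.5$;
  without that dispersion a "missing rate < 20%" filter at an average of
  29% would retain almost nothing, which is not what real pipelines see.
* **Phenotypes** (`simulate_phenotypes()`): `n_qtl` causal markers (default
  40) sampled uniformly, effects $N(0,1)$ rescaled so the true breeding
  values (TBVs) have SD `genetic_sd` = 3 mg/kg; baseline 26 mg/kg;
  environment main effects $N(0, 1.5^2)$ shared across genotypes; and the
  per-record residual variance set *analytically* from the realized TBV
  variance so the lsmean-level heritability equals `h2_target` in
  expectation — no trial-and-error calibration. With three locations this
  yields between-location correlations of genotype means around 0.4–0.6 at
  the study heritabilities, the observed field regime. Targets 0.62–0.84
  mirror the three study populations.

What the generator does **not** emulate: genotyping error beyond
missingness, dominance/epistasis, genotype-by-environment interaction
beyond additive location shifts, selection, drift, or realistic
genome-wide LD decay. Passing tests therefore demonstrate the machinery
and the qualitative design conclusions under an additive world, not field
performance on any particular germplasm.

## 3. The evaluation battery

All experiments share one accuracy definition: the Pearson correlation
between predictions and a reference — lsmeans for real data, simulated
TBVs when truth is available. `kfold_cv()` partitions lines into five
near-equal folds per replicate, re-estimates REML within every training
split (matching per-fit variance estimation in standard mixed-model
software), and defines the replicate accuracy as the *mean of per-fold
correlations* (the pooled-prediction correlation is the other defensible
convention; the fold-mean is used and documented here). Partition validity
(disjoint, exhaustive, near-equal) is asserted property-style.

* `tps_sweep()`: training fractions 10–90%, random subsets predict the
  complement. Cells whose training set would drop below 10 lines are
  flagged, not run.
* `density_sweep()`: fresh uniform marker subsets per replicate. On DH
  simulations accuracy plateaus by a few hundred markers (a DH cross has
  few independently segregating chromosome segments); on LD-block panels
  it keeps rising into the thousands — the package's analogue of the
  published plateau contrast.
* `quality_grid()`: MAF thresholds are strict (`> 0.05` etc., following
  the usual "greater than" wording); missing-rate levels are *inclusive*
  (`<= level`) because a "0% missing" grid level must mean "complete
  markers", which a strict `<` cannot express.
* `scenario_training()`: training sets chosen by lsmean rank (random /
  top / bottom / middle / two tails), validation on the *whole*
  population including the training lines — deliberate fidelity to the
  published design, with `strict_holdout = TRUE` available. Tie-breaks:
  "middle" is the central block symmetric about the median; an odd
  two-tails count puts the extra line in the top tail. Stratifying to the
  two tails maximizes training-set phenotypic variance and, on simulated
  panels at 50% training, gives two-tails > random > middle with means
  near 0.91 / 0.74 / 0.30.
* `cross_population()`: single fit on the training population, validation
  population centered with *training* frequencies, markers intersected by
  id (≥ 50 required). Unrelated populations with disjoint QTL give null
  transfer (|r| < 0.15 in ≥ 90% of seeds at n = 300 per side).
* `mas_prediction()`: the CV machinery restricted to a named marker list.
  The package's MAS emulation selects the top 11 single-marker
  associations in an *independent discovery panel* sharing the trait
  architecture — marker selection the way associated-SNP panels are
  actually built. Against that realistic panel, whole-genome GS wins on DH
  simulations (≈ 0.72 vs 0.62). An oracle subset of the 11 largest-effect
  true QTL would instead capture ~70% of the genetic variance (top-11
  order statistics of 40 squared-normal effects) and *beat* GS — a useful
  reminder that MAS-vs-GS comparisons hinge on how the markers were
  discovered, not only on how many there are.
* `compare_accuracies()`: Welch two-sample t between replicate accuracy
  lists, flagged when both sides are degenerate.

**Seed policy.** Every stochastic operation takes a seed; sweeps derive
per-replicate seeds with `derive_seed(master, index)` (a Lehmer step mod
$2^{31}-1$), so one master seed reproduces an entire experiment
byte-for-byte while keeping substreams decoupled — including the generator
substreams for genotypes, phenotypes, dominant collapse and missingness,
which would otherwise replay overlapping RNG draws.

## 4. Numerical choices and degenerate inputs

* REML search interval $\log\delta \in [-10, 10]$, endpoints checked;
  boundary estimates ($h^2 \to 0$ or $1$) are legitimate outputs.
* Eigenvalues of the projected kinship are clamped at 0 below a relative
  tolerance of $10^{-6}$; anything more negative raises a
  non-positive-semidefinite error.
* Constant phenotype vectors, all-missing markers, fully monomorphic
  marker sets, heterozygous DH parents, fold sizes below 3, and marker-id
  mismatches at prediction are all errors, not silent degradations;
  undefined statistics (accuracy under zero variance, MAF with no calls,
  location correlations with < 3 shared genotypes) return flagged `NA`s.
* Mean imputation is the deliberate default (the ecosystem standard for
  ridge GRMs); it never changes a marker's mean dosage.

## 5. Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run the battery at the package's
chosen desk-scale sizes: populations of 108–300 lines, 500–4,000 markers,
20–50 replicate seeds per experiment and 2–50 CV replicates per cell,
matching the study-condition heritabilities (0.62/0.75/0.84) and the 29%
pre-filter missingness regime. Monte-Carlo recovery statements (e.g.
heritability targets recovered by the 30-seed mean to < 0.08) are phrased
on seed-averaged estimates because the per-seed REML sampling SD on a
~300-line panel of essentially unrelated inbreds is intrinsically ~0.15 —
a property of the study size, not of the estimator.

## 6. Known limitations

* Panels have no population structure or kinship beyond chance; GREML
  variance components on such material are noisy at realistic $n$, and
  transfer experiments lack the subtle relatedness gradients of real
  germplasm collections.
* The additive-only architecture means dominant markers lose information
  solely through dropout and collapse, and MAS-vs-GS contrasts depend on
  the emulated discovery process, as discussed above.
* `ls_means()` deliberately omits incomplete-block (lattice) effects and
  any spatial adjustment.
* No Bayesian-alphabet or GxE prediction models: the scope is the
  RR-BLUP/GBLUP family.
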