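---
title: "Methods: combining abilities, inheritance modes and mixed-model GWAS in diallel panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining abilities, inheritance modes and mixed-model GWAS in diallel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelkit)
```

This vignette documents the statistical models behind `diallelkit`, the
assumptions they make, the tunable parameters that matter, and the
design choices taken where the methodology was genuinely open.

## The diallel design

A diallel panel crosses N homozygous diploid founders pairwise. A full
matrix contains all N² ordered pairs — with 55 founders, 3025 hybrids,
of which 2970 are heterozygous ordered pairs and 55 are selfed
homozygous diploids. Because the heterozygous count quoted for such
panels (2970 = 55 × 54) only matches the *ordered* reading,
`enumerate_full_diallel()` emits ordered pairs, and all phenotype
analyses treat the two reciprocal hybrids of a pair as replicate
measurements of the same unordered cross (diallel theory without
maternal effects; reciprocal differences are not modelled). The GWAS
panel is the half matrix plus diagonal: with 34 founders, 595 hybrids.

Hybrid genotypes are constructed in silico: at a biallelic site the
hybrid is homozygous when both parents carry the same allele and
heterozygous otherwise. This is exact for homozygous founders, which is
why sites with heterozygous or missing founder calls are removed first
(`filter_sites()`).

### Long-range LD pruning

With few founders, many distant sites share an identical founder
genotype column by chance, creating artifactual long-range LD in the
hybrid panel. `prune_long_range_ld()` groups sites into perfect-LD
classes (identical founder pattern); within a class, consecutive sites
at most `max_block_gap` apart on one chromosome form a haplotype block,
and a class occupying more than `max_shared_blocks` (default 2) blocks
keeps only its first two blocks in genomic order. The exact block rule
used on real panels is not uniquely determined by its verbal
description; this reconstruction removes precisely the repeated-pattern
artifact while keeping local LD intact. `max_block_gap` defaults to
25 kb — of the order of a few typical yeast LD blocks; the rule is not
sensitive to this choice for the simulated panels because shared
patterns recur mostly across chromosomes.

## Phenotypes

Replicate colony sizes are normalized per replicate by the matched
control-medium size (`compute_growth_ratios()`); an individual's
phenotype in a condition is the **median** of its replicate ratios,
which is robust to pinning defects and contamination. The replicate
standard deviation (n − 1 denominator) and count are kept: they drive
the error variances of the Griffing decomposition and the tolerance
bands of inheritance classification.

Association scans run on rank-based inverse-normal transformed
phenotypes: the value of rank r among n maps to
`qnorm((r − 0.5)/n)`, ties receiving average ranks. The symmetric
offset 0.5 keeps scores finite and mean-zero; the transform is applied
over exactly the individuals entering each analysis.

## Griffing decomposition and heritability

For the C(N,2) heterozygous crosses,
`z_ij = μ + g_i + g_j + s_ij + e` with

* `μ` — mean of the heterozygous cross phenotypes,
* `ĝ_i = (N−1)/(N−2) · (z̄_i· − μ)`, `z̄_i·` the mean over the N−1
  crosses involving parent i (the inflation factor makes the estimator
  unbiased given that z̄_i· itself contains g_i only N−1 times),
* `ŝ_ij = z_ij − ĝ_i − ĝ_j − μ`.

Selfed (diagonal) hybrids are excluded from estimation: they carry
inbreeding effects the model does not represent. Their predicted value
`μ + 2ĝ_i` is still reported by `expected_phenotypes()`, which is also
why the expected-vs-observed correlation is exactly 1 on the
heterozygous subset (algebraic identity) and drops below 1 only once
diagonal hybrids are included or replicate-level values are compared.

Error terms follow the per-term sampling formulas
`e_gi = (N−1)/(N·(N−2)) · mean_j(σ²_ij/n_ij)` and
`e_sij = (N−3)/(N−1) · σ²_ij/n_ij`, with σ²_ij the replicate variance
of cross (i,j). For the phenotypic-variance denominator the package
uses the direct estimator `σ²_e = mean(σ²_ij/n_ij)` — the sampling
variance of a cross phenotype treated as a mean of n replicates. A
composite expansion of σ²_e in terms of within-family covariances
exists in the diallel literature, but requires cross-sib covariance
terms that replicate tables do not provide; the direct estimator is
self-consistent, vanishes for noiseless data, and reduces to v/n for
constant replicate variance v. Because the phenotype is a median rather
than a mean, `σ²_e` slightly underestimates the true sampling variance
of the median (for n = 6 Gaussian replicates, Var(median) ≈ 0.29 σ²
versus σ²/6 ≈ 0.17 σ²); the surplus is absorbed into the SCA variance,
biasing h² down by a few percent when replicate noise is comparable to
genetic variance. This is quantified by the Monte-Carlo recovery test
(N = 30 founders, 6 replicates, 30 simulation seeds), which sees mean
h² and H² within ±0.08 — in practice within ±0.03 — of their
ground-truth ratios.

Heritabilities are `h² = σ²_A/(σ²_A + Var(ŝ) + σ²_e)` and
`H² = (σ²_A + Var(ŝ))/(σ²_A + Var(ŝ) + σ²_e)` with
`σ²_A = Var(ĝ_i + ĝ_j)` over crosses, both clipped to [0, 1]; a zero
total variance yields missing values with a warning.

## Inheritance modes

With P1 the least-fit and P2 the fittest parent and
MPV = (P1 + P2)/2, seven bands tile the phenotype axis (tolerance
widths from replicate sds): underdominance below `P1 − (σP1 + σHyb)`;
complete dominance toward P1 within `P1 ± (σP1 + σHyb)`; partial
dominance toward P1 up to `MPV − ((σP1+σP2)/2 + σHyb)`; additivity
within `MPV ± ((σP1+σP2)/2 + σHyb)`; then the mirrored P2 bands and
overdominance above `P2 + (σP2 + σHyb)`. The published band table
contains transposed bounds for two rows (an OCR artifact of the
source); the implementation restores the only ordering that is
geometrically consistent (bands nested around P1 < MPV < P2).

Numerical conventions: bands are lower-inclusive/upper-exclusive and
evaluated in left-to-right order, first match winning — this matters
only when large sds make inner bands empty, and makes the call
deterministic. The seven-way call requires separable parents,
`P1 + σP1 < P2 − σP2`; otherwise only underdominance and overdominance
are comparable, judged against the *outer* band bounds directly (inner
bands may overhang the outer bounds when sds are large, so the
first-match index would mislabel extremes). The σ values are replicate
standard deviations (hybrids n = 6, parents n = 54), not standard
errors — the bands are deliberately conservative.

## Mixed-model association

Both encodings are scanned per condition: additive = minor-allele
dosage (minor defined within the hybrid panel, ties toward the
alternate allele; the source-population MAF is an annotation only and
never changes the encoding) and overdominant = heterozygosity
indicator, which contrasts heterozygotes against both homozygote
classes and so picks up dominant and overdominant signals.

The model is `y = μ + gβ + u + ε` with `u ~ N(0, σ²_g K)`. K is the
standardized-dosage kinship `ZZᵀ/m`, rescaled to mean diagonal 1,
computed leaving out the tested site's chromosome (LOCO) to avoid
proximal contamination — hence founders are simulated on 16
chromosomes by default. Per chromosome the null-model variance ratio
`δ = σ²_e/σ²_g` is fitted once by maximum likelihood on the
eigendecomposition of that chromosome's kinship (1-D optimization over
log₁₀δ ∈ [−5, 6], the upper bound acting as the ordinary-least-squares
limit, preferred on ties) and reused for every site on the chromosome —
the standard population-genetics approximation that makes a panel-scale
scan tractable on one CPU. Each site's slope is then generalized least
squares, tested two-sided on n − 2 degrees of freedom. With K = I (or
δ at its OLS limit) the scan equals OLS regression to numerical
precision, which the tests verify to 10⁻⁸. Monomorphic sites return
β = 0, p = 1, flagged; constant phenotypes yield p = 1 everywhere.

### Permutation thresholds

Per condition (and per encoding — permutations are not pooled across
encodings), phenotypes are shuffled uniformly across individuals
`n_perm` times, the genome-wide minimum p recorded for each shuffle,
and the threshold set to the `⌈α·n_perm⌉`-th smallest minimum (5th of
100 at α = 0.05) — the min-p family-wise procedure, matching the
interpretation under which variants passing the threshold have ~5%
family-wise error. A pooled-quantile alternative sits behind
`method = "pooled"`. Calibration is checked by simulation: across 200
fully null scans (595 hybrids × 2000 sites), the fraction declaring
any site significant must fall in the binomial 95% interval around
0.05.

### Effect sizes and variance explained

Cohen's d uses the pooled sd `sqrt((sd₁² + sd₂²)/2)`; the additive
contrast is heterozygotes versus major-allele homozygotes (the larger,
statistically stronger homozygote class), the overdominant contrast
heterozygotes versus all homozygotes. Variance explained is the
squared genotype–phenotype correlation on the transformed scale — a
deliberate reconstruction: panel-scale tools report this quantity
without a published formula, and r² is encoding-agnostic and matches
the reported magnitude range in designed panels where MAFs are large.
It is population-bound: the same allele explains less variance where it
is rarer.

`maf_enrichment()` classifies significant sites by source-population
MAF (low-frequency < 0.05, rare < 0.01 as a subset) and compares
variance explained and |d| of low-frequency versus common sites by
two-sided rank-sum tests. In a half-matrix-plus-diagonal panel every
founder contributes N + 1 allele copies, so the panel allele frequency
of any site equals its founder-sample frequency exactly — a variant
carried homozygously by 3 of 34 founders reaches
105/1190 ≈ 8.8% ≈ 9% in the 595-hybrid panel, which is the mechanism
by which the design makes source-rare variants mappable.

## The synthetic-data generator

`simulate_founders()` draws site minor-allele frequencies from a binned
spectrum; the default places 92.7% of weight below MAF 0.05,
emulating the rare-skewed spectrum of large natural yeast isolate
collections. Attainable founder MAFs are c/N for carrier counts
c ≥ 1, so a bin is realized by drawing a carrier count uniformly among
those falling in it, with a one-carrier floor — the same founder-
sampling boost that the real design exploits. Each site carries a
`maf_source` annotation drawn from its bin, standing for the source-
population frequency. The minor allele is REF or ALT with equal
probability, sites are placed uniformly on 16 chromosomes (LOCO needs
several), and everything is a pure function of its seed.

`simulate_trait_model()` uses the Falconer parameterization —
homozygotes at ±a, heterozygote at d — so complete dominance is
`d = ±a` and over/underdominance `|d| > |a|`; drawn overdominant
deviations use `|d| = 1.5|a| + 0.5·additive_sd` to keep the inequality
strict. Ground-truth GCA/SCA are computed by exhaustively evaluating
genotypic values over all heterozygous crosses and applying the same
Griffing decomposition the estimator targets, so recovery tests compare
like with like. Replicate noise is additive Gaussian on the
growth-ratio scale around a baseline of 1 (`noise = "t4"` provides a
heavy-tailed option to exercise median robustness); the noise
magnitude of real colony ratios is not published, and `env_sd = 0.05`
(5% of the control ratio) was chosen once as a realistic replicate
CV for robot-pinned colonies.

What the generator does **not** emulate: linkage disequilibrium decay
and recombination among founders, population structure, plate-position
effects, and inbreeding depression of the selfed diagonal. Passing
tests therefore demonstrate correctness of the estimators under clean
exchangeable noise, not robustness to spatial artifacts or structure;
on real data the LOCO kinship term is the only structure guard.

## Problem sizes used in the test-suite simulations

Chosen as the smallest sizes at which the targeted behaviours are
cleanly measurable: heritability recovery at N = 30 founders,
6 replicates, 30 seeds; family-wise error calibration at 34 founders
(595 hybrids) × 2000 sites × 100 permutations × 200 null scans;
p-value uniformity at 20 founders × 10⁴ sites; the fixture oracles
(4-parent diallel, 6-observation regression) are exact closed forms.

## Known limitations

* No reciprocal/maternal effects, no Hayman analysis, no REML variance
  components — variance components come from the method-of-moments
  Griffing estimators.
* σ²_e is a mean-based sampling variance while phenotypes are medians
  (bias quantified above).
* The LMM fits the variance ratio under the null per chromosome, not
  per site (no per-site REML), and supports no covariates.
* Variance explained by a set of SNPs cannot be obtained by summing
  per-SNP values: sites in LD share explained variance.
* LD pruning reconstructs a verbal rule; pruned-site counts on real
  panels depend on the original rule and are not expected to match
  exactly.
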