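---
title: "Methods: dissecting nitrogen-use-efficiency traits with multi-locus GWAS, expression colocalization and genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting nitrogen-use-efficiency traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flaxnue)
```

## The problem

Nitrogen use efficiency (NUE) — here, plant dry weight per unit of plant
nitrogen content (mg/mg) — is a quantitative trait of central agronomic
interest in crops such as flax (*Linum usitatissimum*), where seedlings can
be phenotyped under optimum nitrate (N+) and nitrogen-deficient (N−)
treatments. `flaxnue` implements the complete analysis chain for such an
experiment on an inbred association panel:

1. derivation of 21 NUE-related traits from replicate-level measurements;
2. linkage-disequilibrium (LD) and kinship machinery;
3. a two-stage multi-locus mixed-model GWAS producing LOD-scored QTNs
   (quantitative trait nucleotides);
4. QTN validation by allele-effect testing, and LD-based merging of QTNs
   into QTL blocks;
5. differential-expression (DE) testing of RNA-seq counts from contrasting
   genotypes, and colocalization of DEGs with QTL windows;
6. GWAS-assisted genomic selection (GS): GBLUP cross-validation comparing
   QTL-derived marker sets against genome-wide markers.

A seeded synthetic-data generator supplies genotypes, phenotypes, gene
annotations and counts with the statistical structure the pipeline assumes,
so every stage is testable end to end without external data.

## Trait derivation

The eight base measurements are total root length (TRL, cm), root volume
(RV, cm³), root tip count (RT), shoot/root/plant dry weight (SDW, RDW, PDW,
mg) and shoot/root N content (mg), each under N+ and N−. Accession-level
values are best linear unbiased estimates (BLUEs) from a fixed-effect
accession + replicate model; for balanced completely randomized designs
these are the replicate means (the model matters only when cells are
unbalanced). From the BLUEs we derive per accession:

* root/shoot ratio `RS = RDW / SDW` per treatment;
* `NUE = PDW / (shootN + rootN)` per treatment;
* stability indices `100 × x(N−) / x(N+)` for TRL, RV, RT, PDW, SDW and
  NUE (percent; an accession unaffected by N deficiency scores exactly
  100%);
* the Fernandez stress tolerance index
  `NUE_STI = (NUE_N+ × NUE_N−) / mean(NUE_N+)²`, which rewards accessions
  that perform well under both regimes. The literature citation chain for
  this index does not always print the formula; we fix the Fernandez (1992)
  form as the canonical choice. When both NUE columns equal the N+
  population mean, `NUE_STI` is identically 1 — an identity the tests
  assert to 1e−12.

That yields exactly 21 trait columns (`nue_trait_names()`). An R/S
stability index is deliberately not derived: the 21-trait set carries the
five size-trait indices plus the NUE index only. Accessions with a zero
denominator (zero N+ trait value or zero plant N) are excluded with a
logged count rather than propagating infinities.

Treatment/genotype/interaction tests use fixed-effects two-way ANOVA on
the replicate-level data. With balanced data this coincides with the REML
analysis a mixed-model package would report for fixed genotype effects;
without replication the interaction is reported as missing.

## LD, kinship and the relationship matrix

Pairwise LD is the squared Pearson correlation of dosage vectors within a
sliding window of 50 markers (markers, not bp — the convention of the
standard LD software). Dosage correlation equals haplotype-level r² for
fully homozygous material; flax accessions are inbred lines, and the
generator reflects that (default 95% of accessions fully homozygous), so
the approximation is documented rather than harmful.

LD decay is fitted by nonlinear least squares of the Hill–Weir expectation
of r² against distance (single parameter: recombination per bp), with a
binned-median interpolation fallback if the fit fails. `decay_distance()`
inverts the fitted curve at a threshold: 0.1 defines the genome-wide decay
range used for colocalization windows, 0.3 the QTN-grouping criterion.
Profiles that never fall below the threshold within the observed range are
right-censored at the maximum distance rather than extrapolated.

Relatedness comes in two flavors: IBS allele sharing
(`1 − |dᵢ − dⱼ|/2` averaged over markers) for descriptive kinship, and the
VanRaden genomic relationship matrix `G = ZZ′ / (2Σpₖ(1−pₖ))` for mixed
models. Missing dosages are mean-imputed per marker before any matrix
computation — one consistent rule across modules.

## Two-stage multi-locus GWAS

The published analyses this package mirrors run an ensemble of six
multi-locus mixed-model methods and union their findings. Rather than
re-implementing six algorithms, `flaxnue` implements the structure they
share — a kinship-adjusted genome-wide screen followed by a joint
multi-marker fit — once, with configuration variants standing in for the
ensemble members:

* **Null model.** `fit_null_vc()` fits `y = Xβ + g + e` with
  `g ~ N(0, σ²_g G)` by REML, using the spectral decomposition of `G` and
  1-D optimization over `log δ` (`δ = σ²_e/σ²_g`) — the EMMA approach.
  The reported `h²` is the genetic fraction of phenotypic variance,
  `σ²_g·tr(G)/n / (σ²_g·tr(G)/n + σ²_e)`; the trace factor matters because
  the GRM diagonal of an inbred panel is inflated (≈ 1 + f).
* **Stage 1.** A P3D (population parameters previously determined)
  generalized-least-squares Wald test per marker, reusing the null δ̂.
  P3D makes the screen orders of magnitude faster than per-marker REML
  with negligible difference at these scales. Monomorphic or
  covariate-collinear markers get `NA`.
* **Stage 2.** Markers passing the variant's screening threshold
  (default p < 0.01; alternates 0.005, 0.05) enter forward selection by
  extended BIC, `EBIC = n·log(RSS/n) + k·log n + 2γ·log C(M, k)` with
  γ ∈ {0.5, 1} and `M` the genome-wide marker count — the candidates were
  screened from the whole panel, so the model space is size-k subsets of
  all `M` markers, not of the shortlist. Each retained marker is then
  tested by single-term-deletion likelihood ratio;
  `LOD = LRT / (2 ln 10)`, p from χ²₁, effect = the per-dosage additive
  coefficient, and R² = the percentage of phenotypic variance carried by
  the marker term. Only `LOD > 3.0` survives — the sole retention rule, with
  no Bonferroni correction, consistent with the multi-locus philosophy
  that all candidate QTLs are fitted and tested jointly.

With γ = 0.5 and desk-scale panels, the per-marker EBIC acceptance
increment sits almost exactly at the LOD 3 scale, which keeps the
genome-wide null false-positive rate at or below 1 in 1000 markers while
retaining ≥ 80% power for QTLs explaining ≥ 5% of variance in an
oligogenic architecture (both properties are asserted by the test suite).

Per trait and variant the QTN sets are unioned; duplicate marker–trait
records collapse to the maximum-LOD record with all finding variants
listed in a provenance column.

## QTN validation and QTL construction

Each QTN is validated by a two-sided Mann–Whitney U test of the trait
split by homozygous allele class: exact when the smaller class has ≤ 8
members and no ties, normal approximation with tie and continuity
correction otherwise. Heterozygotes are excluded under the inbred-line
assumption (a `het = "pool"` option pools them with the minor class).
QTNs with non-significant allele effects (p ≥ 0.05) are removed as false
positives; classes with fewer than two members make a QTN untestable and
it is likewise removed, with a reason code.

Validated QTNs are merged into QTL blocks chromosome-wise by
single-linkage clustering of positions with link distance
`0.75 × decay_distance(r² = 0.3)`. Two readings of "75% of the maximum LD
decay" are defensible — 75% of the r² = 0.3 grouping distance, or of the
r² = 0.1 genome-wide distance; we follow the explicit r² > 0.3 grouping
criterion and expose both the factor and the threshold as configuration
keys, so the other reading is one argument away. Clustering runs across
traits, so a cluster's trait set defines pleiotropy. The representative
QTN is the member with the largest R², ties broken by smallest position
(deterministic, reproducible IDs of the form `Lu{chrom}_{position}`). A
QTL is *major* when its representative R² strictly exceeds 10%, and
*pleiotropic* with ≥ 2 distinct traits. Simple OLS regressions of traits
on their representative QTN dosages report adjusted R² as the fraction of
variation captured. Favorable-allele counting ranks accessions by the
number of QTLs at which they carry the allele class with the higher trait
mean, and contrasts top and bottom deciles (`round(0.1·n)` accessions).

## Differential expression and colocalization

Counts are normalized by median-of-ratios size factors. Per gene,
`de_test()` fits a negative-binomial GLM (log link) of counts on the
treatment indicator with log size factors as offset; the dispersion is a
per-gene method-of-moments estimate floored at 1e−8, with no
empirical-Bayes shrinkage — a deliberate simplification that is adequate
at four replicates for the planted effect sizes, and is cross-checked
against a reference size-factor implementation in the tests. Significance
requires both `|log2FC| ≥ 1` and Benjamini–Hochberg FDR < 0.05. The
reported fold change is oriented N+ over N− (so "up" = higher under
optimum N), and HN/LN genotypes are tested separately then merged.

Colocalization intersects 1-based closed gene intervals with windows of
±100 kb (the genome-wide LD decay range) around each QTL's representative
QTN, clipped at the chromosome start. Anchoring the window on the
representative position rather than the member span keeps the window a
fixed, interpretable size; the member span is available in the QTL table
for readers who want it.

## GWAS-assisted genomic selection

Five marker sets are compared for predicting NUE_STI:

* **M1** — a seeded uniform random sample of genome-wide markers;
* **M2** — representative QTNs of QTLs for any trait measured under N−;
* **M3** — representative QTNs of QTLs for the target trait itself;
* **M4** — representative QTNs of QTLs for traits positively correlated
  with the target (Pearson r > 0, p < 0.05; the significance gate is a
  configuration key since published set definitions do not state one);
* **M5** — M4 restricted to QTLs whose window holds ≥ 1 DEG.

Markers are coded 1 for the favorable-allele homozygote, −1 for the
alternative, 0 for heterozygotes; the relationship matrix `G = WW′/m` is
invariant to column sign flips, so the coding orientation cannot affect
predictions (asserted in tests). GBLUP is fitted by REML rather than the
Bayesian sampler used by some GS engines: for a single random effect the
two coincide in expectation, and REML is deterministic and testable.
Fivefold cross-validation is repeated (100 times at full scale, 20 in the
bundled scenario), unstratified; per fold, variance components are
re-estimated on the training set and test genetic values are predicted as
`G[test,train](G[train,train] + δ̂I)⁻¹(y_train − μ̂)` (a 1e−8 ridge jitter
handles singular systems). Accuracy is the Pearson correlation between
predicted genetic values and observed phenotypes in the held-out fold,
aggregated as the mean over all fold-results per set. One-way ANOVA with
Tukey HSD and a compact letter display compares the sets.

## What the synthetic generator emulates — and what it does not

The generator's defaults encode the study conditions: ~123–150 inbred
accessions, 15 (or 3, in the bundled reduced scenario) chromosomes, two
subpopulations at Fst 0.1, MAF ≥ 0.05, block LD decaying on the 10–200 kb
scale, 21 correlated traits with planted additive QTLs spanning roughly
0.1–23% of variance, and negative-binomial counts with four replicates and
planted |log2FC| ≥ 1 DEGs placed inside chosen QTL windows.

* **Genotypes.** Haplotypes are mosaics of founder haplotypes with per-gap
  founder-switch probability `1 − exp(−d/L)` (`L` = block length);
  founder alleles are themselves correlated along the chromosome via a
  latent Gaussian AR(1) whose correlation decays three times slower than
  the switch rate, so the copying recombination dominates the realized
  decay. Population structure follows the Balding–Nichols model.
  Accessions are fully homozygous with probability `inbreeding` (default
  0.95), matching a selfing crop. `maf_range` bounds the ancestral
  frequency draw; the hard filter keeps sample MAF ≥ the lower bound,
  mirroring a resequencing panel's MAF filter.
* **Phenotypes.** Per base trait, genetic value = planted additive QTL
  effects + a marker-derived polygenic score (unit variance, correlated
  across traits through a genetic correlation matrix), scaled to the
  requested per-observation h²; residuals are i.i.d. normal, inflated by
  1.3× under N− so N− trait CVs exceed N+ ones, as observed in real
  panels. Treatment mean multipliers shrink size traits under N− while
  raising root/shoot ratio and NUE (shoot N drops more than biomass).
  Plant N content is a latent positive trait with configurable CV — no
  published per-accession N distribution exists to match, so realism is a
  design choice, made once. Values are truncated at zero; with the default
  means and CVs this affects well under 1% of draws.
* **Counts.** NB draws with gene-specific log-normal baselines, library
  size factors, and fold changes applied to the N− samples of the
  specified genotype (dispersion → 0 degrades gracefully to Poisson).
* **Not emulated:** sequence-level reads and alignment, selection and
  demographic realism, epistasis, genotype-by-environment interaction
  beyond the treatment mean shifts, spatial field effects, and
  expression-count structure beyond NB (no outlier genes, no batch
  effects). Passing tests therefore demonstrate correctness of the
  statistical machinery under the stated generative model, not robustness
  to every artifact of real data.

## Numerical choices and degenerate inputs

* REML optimizes `log δ` on [−12, 12] (h² between ~6e−6 and ~1−6e−6);
  eigenvalues are floored at zero, and a GRM with no eigenvalue spread
  (e.g. the identity) is flagged as an unidentifiable variance split.
* Stage-1 tests use the t reference with `n − p − 1` df; markers whose
  projected variance falls below `1e−10 ×` scale are reported missing.
* Forward selection stops on EBIC increase or a perfect fit
  (RSS < 1e−12 of total); aliased markers entering later are dropped and
  logged. A zero-RSS full model yields infinite LOD, which is handled.
* Ties on representative R² break by smallest position; merging is
  order-invariant (sort, then cluster).
* The Hill–Weir fit starts at `rho = 1/median(distance)` with bounds
  [1e−12, 1]; non-convergence falls back to binned medians, flagged in the
  profile's `method`.
* Zero-variance traits are skipped with a message in GWAS; constant
  held-out folds yield `NA` accuracy, excluded from means with a count.

## Problem sizes

The bundled scenario (`demo_config()`) uses 150 accessions, 3 chromosomes
× 1000 markers (≈ 2700 after filtering), 16 planted QTLs of graded effect
driving dry weight and hence NUE_STI, 600 genes, and fivefold CV × 20
repeats — sizes chosen so a complete run takes well under a minute on one
core while preserving the qualitative behavior of the full-scale study
(panel of ~123 accessions, ~273k SNPs, CV × 100). Calibration and recovery
tests run at n = 200–300 with 2000–5000 markers and 20 seeds.

## Known limitations

* Dosage-correlation r² understates haplotype r² for outbred,
  heterozygous material.
* The DE model's moment dispersion without shrinkage loses power at very
  low counts relative to shrinkage-based tools; the planted effect sizes
  and baselines here are comfortably above that regime.
* Cross-validated accuracy on QTL-derived marker sets is optimistically
  biased when the same panel supplied the GWAS — the classic
  GWAS-assisted-GS caveat; an independent validation population is the
  remedy, and is out of scope here.
* The six published multi-locus methods are represented by configuration
  variants of one algorithm, not re-implemented individually; the
  ensemble union, not any single method's internals, is what the pipeline
  reproduces.
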