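---
title: "Methods: post-TWAS gene calling, polytranscriptomic scoring and directional drug enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-TWAS gene calling, polytranscriptomic scoring and directional drug enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytrans)
```

# Scope and model

`polytrans` implements the three analyses that sit downstream of a
case-control GWAS once TWAS/PWAS summary statistics are available:
high-confidence gene calling, polytranscriptomic scoring (PTS) in
external expression cohorts, and directional drug-repurposing
enrichment. It deliberately consumes the *outputs* of SuSiE, FUSION,
SMR/HEIDI and coloc as input tables and does not re-implement those
tools; everything from those tables onward is computed here.

## High-confidence gene calling

A gene is called high-confidence if it satisfies any of:

* it contains **all** variants of a fine-mapping 95% credible set
  (gene-body interval, 1-based inclusive; an optional flanking window is
  exposed and defaults to 0 bp, since the criterion is stated on the gene
  itself);
* an FDR-significant FUSION association with colocalisation evidence
  PP4/(PP3+PP4) strictly greater than 0.8 — the ratio isolates the shared
  causal variant hypothesis (PP4) against linkage (PP3), the only two
  models still in play once the TWAS has established association;
* an FDR-significant SMR association whose HEIDI p-value strictly
  exceeds 0.05 (no evidence of heterogeneity from linkage).

All thresholds are strict inequalities exactly as written; "FDR
significant" is read as Benjamini–Hochberg q < 0.05 (configurable).
Correction pools all expression panels within method, separately for
FUSION and SMR, and separately for expression and protein panels
(`fdr_correct(grouping = c("method", "molecular_type"))`). Gene-level
association tools that ignore direction (MAGMA-style) are intentionally
excluded from high-confidence calling because their hits are prone to LD
confounding.

## Clumping on predicted expression

Nearby TWAS associations are not independent, for the same reason nearby
SNPs are not: their prediction models share or tag the same cis
variation. Before scoring, each (gene, panel) model's SNP weights are
applied to a reference genotype panel, the resulting predicted
expression is standardized, and Pearson correlations are computed for
every pair of units whose genes lie within 500 kb on the same
chromosome. Greedy clumping then ranks associations by ascending
p-value, retains the best remaining unit as lead, and removes every unit
correlated with it at r > 0.95.

Decisions this procedure leaves open in common usage, and how they are
fixed here:

* **Clumping units are (gene, panel) pairs**, not genes. Duplicate-gene
  averaging happens *after* clumping, which implies panel-level units
  enter the clump; two panels' models of the same gene are distance-0
  pairs and may remove one another.
* **Tie-break** for equal p: larger |Z| first, then lexicographic
  (gene, panel) id — fully deterministic.
* **Window anchor**: distance between gene start coordinates by default;
  midpoint anchoring is available (`anchor = "midpoint"`).
* **Out-of-window pairs** carry implicit r = 0 and are never clumped
  together.
* After clumping, a gene retained in several panels contributes the
  arithmetic mean of its retained Z-scores; the gene-level p used for
  thresholding is the two-sided normal tail of that averaged Z, keeping
  weight and selection consistent.

The implementation is validated against an exhaustive oracle that
re-ranks from scratch and recomputes every correlation directly from the
predicted-expression matrix on random instances of up to 50 units.

## Polytranscriptomic scoring and association

Observed log2 expression is standardized gene-wise within each cohort
(n−1 denominator; never pooled across array platforms, matching the
per-platform analysis followed by meta-analysis). The score is the
weighted sum of expression Z-scores over genes passing each p-value
threshold. The default grid is {1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5,
1}; the reported per-stratum result is the max-R² threshold, which is
optimism-prone and flagged as such — no out-of-sample correction is
applied, exactly like standard polygenic-score threshold tuning.

Scores are stratified by panel tissue (all/blood/brain) and by
colocalisation (all associations, or only PP4 > 0.8). Association uses
ordinary linear regression with sex as covariate for all outcomes —
including binary ones, because the liability-scale conversion presumes an
observed-scale linear R². Case-control status uses all samples; site of
onset, age at onset and survival are analysed within cases only. Binary
coding is control/spinal = 0, case/bulbar = 1.

The reported R² is the **incremental** R² of the score over the
covariate-only model (the conventional reading of "variance explained by
the score with sex included"; full-model R² would credit sex to the
score). For binary outcomes it is converted to the liability scale with
the ascertainment-corrected transformation of Lee et al. (2012), with
K = 1/300 for case-control (lifetime risk of ALS) and an arbitrary
K = 0.5 for spinal/bulbar onset; the formula is written out in
`?obs_to_liability_r2` so independent implementations can agree to
machine precision, and the unit tests check it against a separately
transcribed oracle to 1e-10. Per-cohort estimates are pooled by
fixed-effect inverse-variance weighting; pooled R² is summarised as the
sample-size-weighted mean of per-cohort values (IVW applies to the
regression coefficient, not to R², which is not unbiased under pooling).

## Directional drug enrichment

Drug-gene action labels are coded −1 (DECREASED_EXPRESSION,
NEGATIVE_RESPONSE, OPPOSITE_RESPONSE), +1 (INCREASED_EXPRESSION,
POSITIVE_RESPONSE) or 0 (anything else), and drugs with fewer than two
target genes with available TWAS statistics are skipped. Per drug, gene
TWAS Z-scores are regressed on the coded direction vector by generalized
least squares with error covariance equal to the predicted-expression
correlation matrix restricted to the tested genes (identity beyond known
pairs, ridge-stabilised if a correlation entry makes it non-PD). The
reported enrichment Z is the negated slope Z, so a drug that
down-regulates risk-raising genes (and up-regulates risk-lowering ones)
scores positive = protective. This is a transparent surrogate for
direction-aware TWAS gene-set enrichment: it preserves the two essential
properties — directionality and co-regulation awareness — without
claiming bit-compatibility with any external mixed-model tool. With
identity covariance it reduces exactly to the OLS slope t-test; with
exactly two tested genes the residual degrees of freedom are zero, so
the unit null variance of TWAS Z-scores is used in place of an estimated
error variance (a z-test).

ATC level-3 classes with at least five drugs are tested by Wilcoxon
rank-sum of in-group versus all other drug statistics: one-sided
(greater) for unsigned external methods, two-sided with the signed
standardized group Z for the directional method. The exact distribution
is used when both sides have ≤ 25 drugs and no ties; otherwise the
normal approximation with tie correction. BH correction is applied
across tested groups per method; when external per-panel statistics are
supplied, the test is run per panel (matching per-panel displays of
class enrichment) — pooling is a caller choice.

## Observed differential expression and concordance

Observed case-control differential expression is the Pearson
(point-biserial) correlation of expression with status, per cohort,
meta-analysed on the Fisher-z scale with weights n−3 (the raw-r scale is
available behind a flag for sensitivity) and BH-corrected across genes.
The DE analysis is unadjusted by default — the association analysis
adjusts for sex, but the DE step is specified only as a correlation; a
covariate option (partial correlation) is provided. A high-confidence
gene with observed q < 0.05 is *concordant* if its TWAS Z and observed
meta correlation share a sign, *discordant* otherwise; remaining genes
are `observed_not_significant`. Only observed significance is required —
the TWAS side has already passed the high-confidence filter.

# The synthetic-data generator

The generator is the package's study design: its defaults are the
conditions under which all properties are demonstrated.

* 500 genes on 5 chromosomes, non-overlapping, 1-based inclusive
  coordinates; inter-gene gaps of 20–300 kb so that neighbours straddle
  the 500 kb window both ways.
* Reference panel of 200 individuals; 10 unlinked variants per gene with
  MAF ~ Uniform(0.05, 0.5). Variants are independent binomial draws: LD
  realism is unnecessary because clumping operates on predicted
  expression, whose correlation is induced directly through shared
  SNP-weight vectors (a cross-panel similarity parameter controls how
  often two panels' models of a gene correlate above 0.95).
* Four panels (alternating blood/brain tissue and FUSION/SMR method),
  each gene present in a panel with probability 0.6. Signal genes (10%)
  draw Z ~ N(±4, 1); half of them truly colocalise (PP4 near 1 via
  Beta(40, 2), HEIDI p > 0.05); non-colocalising rows are constructed so
  the PP4 ratio cannot exceed 0.8. SMR rows also carry a PP4 value so the
  PP4-stratified scoring path can use them (the PP4 > 0.8 restriction is
  applied to whatever rows carry a PP4).
* Two cohorts of 300 cases + 300 controls (the scale of the two-platform
  whole-blood case-control series the design emulates), log2 expression
  with unit residual SD. Cases shift by ±0.3 SD on signal genes; 70% of
  signal genes shift concordantly with their TWAS direction. The 0.7
  default makes the score predictive while leaving a substantial
  discordant minority, the qualitative pattern seen when predicted and
  observed differential expression are compared in practice.
* Survival is uncensored, positive, log-normal (median 2.5 years):
  survival enters the association analysis as a continuous linear-model
  outcome, and no censoring mechanism is modelled — an explicitly flagged
  simplification.
* 60 drugs in 8 ATC groups, Poisson(5) targets each; 15% planted
  protective (anti-aligned with true TWAS directions at 90% fidelity,
  preferentially targeting signal genes and concentrated in a quarter of
  the ATC groups), 15% harmful, the rest neutral.

What the generator does **not** emulate: raw genotype-phenotype GWAS
data, realistic LD panels, probe-level microarray artefacts, batch
effects, or informative censoring. Passing tests therefore demonstrate
the *statistical mechanics* of the pipeline — calibration, parameter
recovery, rule correctness, determinism — not robustness to those
real-data complications.

# Numerical choices and degenerate inputs

* All decision thresholds are strict inequalities; boundary cases
  (ratio exactly 0.8, HEIDI p exactly 0.05) fail.
* Zero-variance predicted expression or expression genes are dropped
  with warnings; perfect DE correlations are shrunk to ±(1−1e−12) before
  the Fisher transform.
* Constant direction vectors make a drug's slope inestimable: skipped.
* Non-positive-definite drug covariances get an escalating ridge
  (1e-8 up, logged).
* Every generator is a pure function of (config, seed) via fixed
  per-stage seed offsets, so stages are individually reproducible
  regardless of call order; the pipeline writes a checksum manifest and
  is byte-reproducible.

# Problem sizes used in validation

The test suite exercises: clumping oracle equivalence on 200 random
instances of up to 50 units; PTS effect-size recovery on two-cohort data
(300+300 per cohort, 500 genes, full concordance) over the effect grid
{0, 0.1, 0.2, 0.3, 0.5} with 50 replicates per point, with the
zero-effect mean checked against the analytic null expectation
E[R²] ≈ 1/(n−1) mapped through the liability transform; null calibration
of association p-values over 200 replicates and of the drug/ATC FDR
layers over 200 label-permuted replicates; and planted-protective-drug
recovery over 50 replicates. These sizes were chosen as the smallest at
which the binomial/Spearman acceptance bounds are meaningful.

# Known limitations

* The max-R² threshold report is optimistic; treat it as within-sample.
* The GLS enrichment surrogate shares direction and covariance awareness
  with mixed-model TWAS gene-set enrichment but is not that estimator.
* Liability conversion assumes the observed-scale linear-probability
  R² is small-to-moderate; it is not a logistic pseudo-R².
* Meta-analysed R² is a weighted summary, not a pooled estimate with a
  standard error.
* The synthetic phenotypes make clinical outcomes (site, age, survival)
  null by construction; only case-control status carries signal.
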