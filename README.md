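# polytrans

Post-GWAS integration of transcriptome- and proteome-wide association
study (TWAS/PWAS) results for complex disease, built around three
downstream analyses that typically follow a large case-control GWAS such
as the recent amyotrophic lateral sclerosis (ALS) studies:

1. **High-confidence gene calling** — combining fine-mapping credible
   sets, FUSION-style colocalisation (PP4/(PP3+PP4) > 0.8) and SMR/HEIDI
   evidence (HEIDI p > 0.05) with per-method FDR correction into a single
   audited gene list.
2. **Polytranscriptomic scoring (PTS)** — per-individual risk scores from
   observed expression, weighted by TWAS Z-scores after clumping on a
   *predicted-expression* correlation matrix (r > 0.95 within 500 kb) and
   p-value thresholding, with liability-scale variance conversion and
   inverse-variance meta-analysis across cohorts.
3. **Directional drug repurposing** — signed coding of drug-gene
   interaction labels, a co-regulation-aware generalized-least-squares
   enrichment test per drug, and Wilcoxon rank-sum enrichment of level-3
   ATC pharmacological classes, plus concordance classification of
   predicted versus observed case-control differential expression.

A first-class synthetic-data module generates every input the pipeline
consumes — gene maps, reference genotypes, TWAS/SMR tables with SNP
weights, credible sets, two-platform case-control expression cohorts, and
a DrugTargetor-like drug database — with known embedded ground truth, so
the full analysis runs and validates end-to-end with zero downloads.

## The core quantities

For sample *s* and threshold *t*, the polytranscriptomic score is

    PTS_s(t) = sum over genes g with p_g <= t of  Z_g^TWAS * z_gs

where `z_gs` is the gene's standardized observed expression and
`Z_g^TWAS` the (duplicate-averaged) TWAS Z-score after clumping. The
association of PTS with case-control status is fitted by linear
regression with sex as a covariate; the incremental R² of the score is
converted to the liability scale with the ascertainment-corrected
transformation (prevalence K = 1/300 for case-control, K = 0.5 for
spinal/bulbar site of onset):

    R²_liab = C·R²_obs / (1 + C·θ·R²_obs),   C = K(1−K)/φ(t_K)² · K(1−K)/(P(1−P))

Per-drug enrichment regresses gene TWAS Z-scores on the drug's coded
direction vector (−1 decrease / +1 increase / 0 non-directional) by GLS
with the predicted-expression correlation as error covariance; the
reported Z is negated so that **positive Z = predicted risk reduction**.

## Worked example

```r
library(polytrans)
cfg <- pipeline_config(synthetic = synthetic_config(seed = 42))
res <- run_pipeline(cfg, "run", quiet = TRUE)

attr(res$high_confidence, "n_genes")
#> [1] 25

m <- res$pts_meta
cc <- m[m$outcome == "case_control" & m$stratum == "all.any", ]
cc[which.max(cc$r2_liability), c("threshold", "beta", "p", "r2_obs", "r2_liability")]
#>    threshold    beta        p r2_obs r2_liability
#> 50     0.001 0.00533 1.22e-31  0.103       0.0488

attr(res$concordance, "counts")
#>     concordant    discordant observed_not_significant
#>             19             6                        0
```

Of 500 simulated genes (10% carrying a true TWAS signal), 25 are called
high-confidence; the case-control PTS meta-analysed over the two
600-sample cohorts explains ~4.9% of liability-scale variance at its best
threshold (p ≈ 1e-31), and 19 of the 25 high-confidence genes show
observed differential expression concordant with their TWAS direction —
matching the 70% concordance embedded by the generator.

Every stage writes headered TSVs plus a checksum manifest under the run
directory; re-running with the same configuration reproduces identical
checksums (`pipeline_demo()` is a seconds-scale end-to-end smoke test).

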