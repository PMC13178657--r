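# mihcTME

Spatial single-cell proteotyping of the tumor microenvironment (TME) from
multiplex immunohistochemistry (mIHC), built around the question that drives
modern immuno-oncology biomarker work: *which cellular contexture of a
metastatic NSCLC tumor predicts long-term benefit from PD-1/PD-L1 checkpoint
inhibitors (ICIs)?*

The package takes per-cell marker-intensity tables (one row per segmented
cell: x/y position in µm plus 29 marker intensities) and runs the full
analysis chain:

* **Hierarchical gating** of binary marker calls into a mutually exclusive
  cell taxonomy (cancer `panCK⁺CD45⁻`, CAF `panCK⁻CD45⁻FAP⁺`, T/NK/B/myeloid
  lineages, including Trm-like `CD39⁺CD103⁺` CD8 T cells) — ≥20 subset
  labels.
* **Tissue segmentation** of each field into tumor-cell-nest (TN) and
  intratumoral-stroma (ISA) compartments via a Gaussian kernel density of
  cancer-cell positions (pitch 20 µm, bandwidth 30 µm, threshold
  τ = 2.5×10⁻⁴ cells/µm²).
* **Quantification**: compartment densities (cells/mm²), phenotype
  positivity fractions with absence exclusion, effector-to-target ratios,
  assembled into a patients × features matrix.
* **Unsupervised fTME discovery**: z-scored key features (Ki-67⁺ Trm-like
  CD8 density in TN, CD206⁺ M2-TAM density, FAP positivity in ISA stroma)
  clustered by average linkage under the Cluster 3.0 *uncentered
  correlation* distance, `s(x,y) = Σxy / (√Σx² √Σy²)`, cut at k = 10, with
  favorable clusters selected by the centroid-sign rule
  `z(Ki-67⁺Trm) > 0 ∧ z(CD206⁺TAM) < 0 ∧ z(FAP) < 0`.
* **Survival statistics**: durable-clinical-benefit (DCB) classification
  (PFS ≥ 365 d), Kaplan–Meier + log-rank, Cox proportional hazards (Efron
  ties, Wald CIs), Mann–Whitney/Fisher/Spearman, Benjamini–Hochberg FDR,
  and a hazard-ratio/p-value sweep over every TME profile.
* **Expression companion**: Welch-t differential expression over a 726-gene
  panel, mean-z signature scores, and the composite `CD8B^hi MRC1^lo FAP^lo`
  fTME-like transcriptional profile.

Because the motivating study's patient-level data are not public, the package
includes a **calibrated synthetic-cohort generator** (`generateCohort`)
emulating the study conditions: 103 patients (81 ICI-treated; 19
EGFR-mutant/13 ALK/71 wild-type; 30 DCB/49 non-DCB/2 early-censored,
exactly), spatial tissue structure (cancer-cell nests, stromal corridors,
compartment-biased infiltration), a proportional-hazards outcome model with
planted effects (PFS HR 0.15 and OS HR 0.11 for DCB vs non-DCB; multivariable
HR 1.79 for low vs high TN CD8 density), and an 11-patient planted
favorable-TME subset. See the methods vignette
(`vignettes/spatial-tme-profiling.Rmd`) for the model and its assumptions.

## Worked example

```r
library(mihcTME)

cfg    <- defaultCohortConfig()              # packaged calibration (seed 42)
cohort <- generateCohort(cfg, tissues = "ici")
cohort
#> SyntheticCohort: 103 patients, 81 tissues, expression: 27 x 726

cl  <- clinicalTable(cohort)
ici <- cl$ici_treated == 1
table(classifyDCB(cl$pfs_days[ici], cl$pfs_event[ici]))
#>            DCB        non-DCB early-censored
#>             30             49              2

## PFS hazard ratio for the planted benefit class (truth 0.15)
fit <- coxFit(cl$pfs_days[ici], cl$pfs_event[ici],
              data.frame(dcb = as.integer(truthTable(cohort)$outcome_class[ici] == "DCB")))
round(fit$table[, c("hr", "lo", "hi")], 4)
#>       hr     lo     hi
#> 1 0.1864 0.1016 0.3422

## full pipeline: gate -> segment -> quantify -> cluster -> sweep
out <- runPipeline(cohort)
out$clustering$result
#> ClusterResult: 81 patients in 10 clusters (2 favorable: 3, 10)

head(out$sweep[order(out$sweep$p_logrank), c("feature", "hr", "p_logrank")], 3)
#>               feature       hr    p_logrank
#> 28      et_trm_cd8_tn 2.549591 0.0001809119
#> 4  cd8_til_density_tn 2.350145 0.0005536559
#> 6  trm_cd8_density_tn 2.282283 0.0009937396
```

Reading the output: the 1-year classifier reproduces the configured outcome
classes exactly; the single-cohort Cox estimate (0.19, CI 0.10–0.34) brackets
the planted HR 0.15; the two favorable clusters contain the 11 planted
favorable-TME patients; and the hazard-ratio sweep ranks tumor-nest CD8
features (E/T ratio of Trm-like CD8, TN CD8 density) as the strongest
unfavorable-when-low profiles — HR > 1 means the below-median group
progresses faster.

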