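# spatialTME

Analysis of single-cell spatial proteomics (multiplex immunohistochemistry,
mIHC) data from tissue regions of the tumor microenvironment (TME), built
for studies that ask how immunotherapy reshapes T cell phenotype and
spatial organization — e.g. pancreatic ductal adenocarcinoma resections
from treatment-naive patients versus patients treated with neoadjuvant
agonistic CD40 (aCD40) antibody, with disease-free survival (DFS) follow-up.

The input is tabular single-cell data as produced by any mIHC/CODEX/MIBI
image-processing stack: per-cell centroid coordinates and thresholded 0/1
marker positivity, plus region metadata (patient, treatment cohort,
histopathologic site annotation — tumor T, immune aggregate IA,
tumor-adjacent stroma TAS, normal-adjacent pancreas NAP — and tissue
area). Image acquisition, segmentation and thresholding are upstream and
out of scope.

## What it computes

1. **Hierarchical phenotyping.** A declarative, exclusive gating hierarchy
   (YAML; shipped default has 23 terminal lineages/states, 18 of them
   T cell states) assigns every cell exactly one state; siblings are
   evaluated in order and the first match wins.
2. **T cell functionality barcodes.** Every T cell gets a 10-bit barcode
   over the fixed marker alphabet (TOX1, TIM3, TCF-1, CD38, PD-1, EOMES,
   CD39, CD44, LAG-3, T-BET); Ki-67 and GrzB remain separate
   proliferation/cytotoxicity flags. At most 2^10 = 1024 barcodes exist.
3. **TME features per region.** State densities (counts / tissue area),
   barcode densities, and cell–cell spatial interactions: unordered cell
   pairs with centroid distance <= 20 um, normalized by the summed
   densities of the distinct states involved so abundant states do not
   skew the score.
4. **Per-site classification.** One elastic-net logistic model
   (`l1_ratio = 0.5`) per histopathologic site, under leave-one-patient-out
   cross-validation (LOPO): all of a patient's regions are held out
   together so the model can never learn patient identity. Inside every
   fold: `log10(x+1)` transform, min-max [0,1] scaling fitted on the train
   side only (test values clipped), and SMOTE oversampling of the minority
   class. Held-out predictions are pooled into a single confusion matrix;
   accuracy, positive-class F1 and rank-statistic AUC are reported.
5. **Interpretation.** Exact linear SHAP values (background = fold-train
   feature mean) pooled over held-out regions give per-feature importance
   (mean |SHAP|) and direction; top features are tested between groups by
   Mann-Whitney U with Benjamini-Hochberg correction; predictive barcodes
   are correlated by the T-state profiles expressing them and clustered
   (average linkage on 1 − r).
6. **Recurrent cellular neighborhoods (RCNs).** Every cell's neighborhood
   is its 60-um ball (seed included); neighborhood composition vectors
   are K-means-clustered with the cluster count chosen by a kneedle-style
   elbow rule; barcode RCN-residency profiles are clustered (Ward), and
   per-RCN Ki-67/GrzB fractions are compared to the overall T cell
   baseline (T_REGs excluded for GrzB).
7. **Synthetic cohorts.** `synth_config()` / `generate_cohort()` generate
   mIHC-like datasets — clustered immune-aggregate point patterns,
   state-conditional marker positivity that exactly satisfies the gating
   hierarchy, planted cohort/DFS effects, per-(patient, region) RNG
   streams — so every stage of the pipeline is testable without any
   patient data.

## Worked example

```r
library(spatialTME)

gating <- load_gating_config()          # 23 leaves, 18 T states
cohort <- generate_cohort(synth_config(seed = 42,
  n_patients = c(naive = 8, aCD40 = 8),
  regions_per_patient = c(IA = 2), cells_per_region = 200), gating)

cells <- assign_barcodes(assign_states(cohort$cells, gating), gating)
fm    <- build_feature_matrix(cells, cohort$regions, gating)
dim(fm)
#> [1]  32 634

model <- run_lopo(fm, cohort$regions, cohort$patients,
                  task = "treatment", site = "IA", seed = 1)
model
#> Leave-one-patient-out elastic net (treatment task, site IA)
#>   16 folds, 32 pooled regions; positive class 'aCD40'
#>   accuracy 0.844 | F1 0.839 | AUC 0.965

head(top_features(model, 5))
#>                          feature importance direction
#> 1 barcode:PD-1+CD44+LAG-3+T-BET+  0.2706629         1
#> 2            barcode:EOMES+CD44+  0.2474774        -1
#> 3                 barcode:EOMES+  0.2385825        -1
#> 4                 density:B cell  0.1830938        -1
#> 5                  barcode:TOX1+  0.1467726        -1
```

The feature matrix has one row per tissue region and 634 columns here
(23 state densities + the barcodes and interaction pairs observed in this
cohort). The model separates the cohorts almost perfectly (pooled AUC
0.965 over 32 held-out regions), and the SHAP ranking surfaces the
planted biology: a CD44+/T-BET+-containing barcode pushes predictions
toward aCD40 (direction +1), while TOX1/EOMES barcodes and B cell density
push toward treatment-naive — exactly the effects
`synth_effects()` plants. `run_treatment_analysis()` and
`run_dfs_analysis()` wrap the full multi-site pipeline including the
statistics, barcode-profile clustering and (for DFS) the RCN stage.

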