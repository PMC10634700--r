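---
title: "Methods: phenotyping, spatial features, and patient-held-out modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, spatial features, and patient-held-out modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical and computational choices behind
spatialTME: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## The data model

A dataset is three tables. The **cell table** has one row per segmented
cell: a region identifier, centroid coordinates in microns (per-region
frame; no global slide frame is assumed, because every spatial operator
here acts within a region), and binary positivity for each panel marker.
Positivity is consumed as already-thresholded 0/1 — threshold setting
belongs to the imaging stack, and any intensity columns are ignored. The
**region table** maps regions to patients, treatment cohorts (`naive`,
`aCD40`), histopathologic sites (`T`, `IA`, `TAS`, `NAP`) and tissue
areas in mm². The **patient table** carries disease-free survival in
months for the treated cohort. `validate_dataset()` collects
referential-integrity findings with severities rather than failing fast,
so callers decide what aborts.

## Exclusive hierarchical gating

Phenotyping is rule-based, not probabilistic: a YAML hierarchy of gates,
each a conjunction of required-positive and required-negative markers
plus an optional *any-of* clause (at least one of a set positive). The
any-of clause exists because canonical exhaustion states are defined
disjunctively — e.g. an exhausted CD8 cell is PD-1⁺ with at least one of
TIM3/LAG-3 — and pure conjunctions cannot express that. Siblings are
evaluated in listed order and the first match wins, which is what makes
the populations exclusive and the assignment a partition: every cell
gets exactly one of the 23 terminal states (18 T states), with a
residual `Other` leaf guaranteeing exhaustiveness.

The default T-state predicates (T_NAIVE, T_EFF, T_EM, T_EMRA, T_EX,
T_TEX over CD44/TCF-1/T-BET/EOMES/PD-1/TIM3/LAG-3/TOX1) are shipped
configuration, not code. The analysis machinery is deliberately agnostic
to the immunological content of the predicates: correctness is defined
against the configuration, and a user with a different panel or gating
scheme supplies a different file. The 23rd leaf is the residual class;
the named lineages plus the 18 T states account for 22.

`derive_state_constraints()` inverts the hierarchy: for each leaf it
computes forced-positive/forced-negative marker sets such that *any*
completion of the free markers gates back to exactly that leaf. Because
first-match-wins semantics means a cell must also *fail* every earlier
sibling, the derivation is a small backtracking search that contradicts
each earlier sibling by forcing one of its markers the opposite way.
This is what lets the synthetic generator plant states that phenotyping
recovers with zero error — a property the test suite asserts for every
leaf.

## Functionality barcodes

Every T cell's barcode is its positivity over the fixed, ordered
10-marker alphabet (TOX1, TIM3, TCF-1, CD38, PD-1, EOMES, CD39, CD44,
LAG-3, T-BET); the canonical name concatenates the positive markers in
alphabet order (`"CD44+T-BET+"`, or `"NEG"`). Ki-67 and GrzB are
deliberately excluded: they flag proliferation and cytotoxicity and are
analysed separately in the RCN stage. The space is bounded at 1024
distinct words, and observed inventories are always far smaller.

## TME features

Three families, all per region and all non-negative:

* **State densities** — raw counts divided by tissue area (cells/mm²).
* **Barcode densities** — per-barcode T cell counts over area.
* **Spatial interactions** — unordered pairs of cells with centroid
  distance ≤ 20 µm (inclusive; distances are compared squared so the
  boundary is exact), keyed by the unordered state pair and normalized
  by the summed densities of the *distinct* states involved. The
  distinct-state reading means a same-state pair divides by that state's
  density once — the literal reading of "summed densities of the states
  involved" — and is pinned by a regression test. Whether same-state
  pairs should be counted ordered or unordered is not decidable from
  first principles; unordered (each cell pair once) was chosen and
  documented.

The neighbor search grid-bins points at the radius scale and compares
only the 3×3 bin neighborhood; it is exactly equal (not approximately)
to the brute-force O(n²) scan, which the tests assert on random regions
up to n = 2000.

The assembled feature matrix has a fixed column order — densities in
taxonomy order, then barcodes and interaction pairs lexicographically —
and stores zeros, never missing values, for features unobserved in a
region. Raw values are stored; the log10+1/min-max transform happens
inside each cross-validation fold, never globally, because fitting any
scaler on pooled data before splitting would leak test information.

## Patient-held-out elastic-net classification

Predictions are made per region to maximize sample size, with one model
per histopathologic site. The cross-validation unit is the **patient**:
each fold holds out all of one patient's regions, so the model cannot
score by recognizing patient-specific signatures. Inside every fold, in
order:

1. `log10(x+1)` elementwise, then per-column min-max to [0,1] fitted on
   the train rows only; test rows transformed with the train scaler and
   clipped to [0,1]. Columns constant in train map to 0 — they carry no
   information and this avoids a zero division.
2. SMOTE: the minority class is up-sampled to parity by convex
   combinations of a minority sample and one of its k = min(5, m−1)
   nearest minority neighbors; with a single minority sample the step is
   skipped with a warning. The SMOTE stream is seeded from the held-out
   patient's identifier, so results are invariant to fold execution
   order.
3. An elastic-net logistic fit at mixing ratio 0.5 (equal lasso/ridge)
   via glmnet. The regularization strength is the fixed inverse-strength
   constant C = 1 shared across folds, mapped to the per-sample penalty
   `lambda = 1/(C·n)` so the objective equals the conventional
   sum-of-losses parameterisation; the convex fit is deterministic
   (coordinate descent, tolerance 1e-9, bounded iterations).

Held-out predictions are pooled across folds into one confusion matrix;
accuracy and positive-class F1 (positive class: `aCD40` for the
treatment task, `long` for DFS) come from that matrix, and AUC is the
rank statistic on pooled probabilities with midranks for ties — pooled
rather than per-fold-averaged, to match the pooled confusion matrix.

DFS labels come from the median split of the treated cohort's survival
months: strictly above the median is `long`, at or below is `short` (a
patient exactly at the median does not strictly exceed it). The DFS task
is restricted to treated regions and never models NAP, which has too few
regions.

For a linear margin the Shapley attribution has the exact closed form
`w_i (x_i − μ_i)`; the background μ is the fold-train feature mean
(pre-SMOTE, i.e. the real regions), and attributions sum to
`f(x) − f(μ)` by construction — asserted to 1e-6 per row. Importance is
the mean |SHAP| over pooled held-out rows; direction is the sign of the
feature-versus-SHAP correlation, which for a linear model equals the
coefficient's sign toward the positive class.

## Statistics

Top model features are compared between groups with two-sided
Mann-Whitney U tests on the raw feature values; since the test is
rank-based and both model transforms are strictly monotone, the choice
of scale is provably immaterial (a test asserts p-value equality across
scales). The exact null is used up to combined n = 20 without ties,
otherwise the tie-corrected normal approximation. Benjamini-Hochberg
correction is applied per analysis family (one model's top-feature set)
at α = 0.05.

## Recurrent cellular neighborhoods

Every cell's neighborhood is the set of cells within 60 µm of its
centroid, *including itself* — its own distance is 0, and seed inclusion
(configurable) keeps isolated cells well-defined as one-hot
compositions. Composition vectors over the 23 states are pooled across
the treated IA regions and K-means-clustered (10 restarts, fixed seed)
for each candidate K; the best-of-restarts inertia curve must be
non-increasing (violations are refitted with more restarts), and K is
chosen by the kneedle-style elbow: the candidate at maximum
perpendicular distance from the chord joining the first and last
normalized curve points, anchors excluded, ties to the smallest K. The
default candidate range is 2–12. RCN labels are sorted by descending
member count so RCN1 is always the largest — stable labels across runs.

Residency analysis takes the DFS model's top predictive barcodes,
restricts each barcode's T cells to patients of the DFS group it
predicts, and computes the fraction of those cells in each RCN (rows sum
to 1). Rows are log10+1-transformed and hierarchically clustered (Ward
linkage, Euclidean distance) with a 2-group cut. Per-RCN Ki-67 and GrzB
fractions are reported with their raw counts — low-count RCNs deserve
caution — against the overall in-scope baseline; T_REG states are
excluded from the GrzB analysis, since regulatory cells are not expected
cytotoxic effectors.

Pearson correlation for barcode-profile similarity and
average-linkage/Ward clustering choices are parameters: the procedures
require only "a correlation" and "a hierarchical clustering", and the
defaults are the field's common choices. Barcode-profile cluster count
is likewise a parameter (4 by default), not auto-selected.

## The synthetic cohort generator

`synth_config()` defaults describe the study conditions the package is
validated under: 18 treatment-naive and 11 treated patients (the
real-world cohort split this design targets), a fixed complement of
regions per patient (T:3, IA:2, TAS:2, NAP:1 — 232 regions), and 250
cells per region. Cell counts and areas aim at structural realism, not
at any cohort's absolute densities. Site-specific state frequencies
encode the expected tissue composition (epithelial-dominant T regions,
T/B-cell-rich IAs, myeloid-dominant NAP; CD4:CD8 ≈ 2:1 with most T cells
in the CD44-stratified "other" states). IA regions use a clustered point
process — Gaussian clusters into which T and B cells are preferentially
placed — emulating immune aggregates; other sites are uniform.

Marker positivity is Bernoulli per marker with the planted state's
gating constraints forced, so phenotyping recovers planted states
exactly. Planted effects are multiplicative: treatment shifts enrich
CD44/T-BET/CD39/TIM3/TCF-1 barcode probabilities and Th1/mesenchymal
densities in the treated cohort while depleting TOX1/EOMES; DFS shifts
(IA regions only) enrich CD44/CD38/CD39/TIM3/LAG-3 and deplete
TOX1/PD-1 for long survivors. Shift sizes of 1.4–2.2× were chosen once
as effects a well-powered region-level model should detect cleanly; a
shifted probability that would leave [0,1] is clamped with a warning.
DFS months are drawn from two shifted log-normals (medians ≈ 5 and 20
months, σ_log = 0.25) so the median split recovers the planted grouping.
Each region draws from its own RNG stream derived from the (patient,
site, replicate) triple, so adding a region never perturbs any other.

What the generator does **not** emulate: marker correlation beyond what
the gating hierarchy induces, segmentation artifacts, staining batch
effects, inter-patient heterogeneity beyond the planted effects, or
realistic absolute densities. Passing tests therefore demonstrate that
the pipeline recovers structure it is pointed at under clean conditions
— not that it would perform identically on real tissue.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run
comfortably on a single CPU: module tests use cohorts of 4–16 patients
with 100–500 cells per region; the chance-level permutation check uses
8–10 patients per cohort with 3–4 IA regions each, the smallest scale at
which leave-one-patient-out pessimism (a known small-sample CV bias that
pulls null AUC below 0.5) no longer dominates the null distribution; the
acceptance script runs the full default conditions (232 regions, 58 000
cells) end to end. Determinism is asserted by running the full pipeline
twice and requiring identical report bundles.

Other numerical choices: distances compared squared (exact inclusive
boundaries); feature matrices dense with explicit zeros; glmnet called
without internal standardization (the min-max scaler already fixes the
scale); K-means inertia monotonicity enforced by refitting; degenerate
inputs (all-constant features, single-class folds, zero expressing
cells, identical compositions) handled by documented fallbacks rather
than errors where a fallback is well-defined.

## Known limitations

* Gating quality is bounded by the configuration: the machinery
  validates structure (cycles, unreachable siblings, unknown markers)
  but cannot know whether predicates are immunologically right.
* Region-level modelling treats a patient's regions as exchangeable
  within a site; LOPO prevents identity leakage but not within-patient
  correlation of the truth labels (inherent to the design).
* The elbow rule needs the true K inside the candidate range and a
  non-degenerate curve; on data with no neighborhood structure it still
  returns some K, so RCN outputs should be read alongside the inertia
  curve.
* SMOTE operates in the preprocessed feature space; with very few
  minority patients the synthetic samples interpolate a handful of
  regions and class balance is nominal rather than informative.
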