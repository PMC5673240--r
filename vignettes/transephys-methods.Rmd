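---
title: "Methods: relating cell-type transcriptomes to intrinsic electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating cell-type transcriptomes to intrinsic electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neuron types differ enormously in their intrinsic electrical properties —
resting potential, input resistance, spike shape, maximal firing rate — and
those differences must ultimately be written in gene expression. `transephys`
implements a discovery → validation analysis that asks, across a collection
of cell types, which genes' expression levels co-vary with which
electrophysiological (ephys) properties, and how far multivariate expression
patterns can *predict* a cell type's ephys values.

The package operates on two kinds of raw material:

* **Cell-type expression**: pooled-cell microarray samples (log2 intensity)
  or single-cell RNA-seq (TPM), each sample labeled with a cell type (or
  cre-line) and optionally an animal age.
* **Curated ephys measurements**: article-level population means of 11
  registered properties (`ephys_properties()`), each annotated with the
  methodological metadata that drives cross-laboratory variability: species,
  preparation, electrode type, junction-potential handling, animal age, and
  recording temperature.

Because the two modalities almost never come from the same study, the unit
of analysis is the *cell type*: expression is summarized per type, ephys is
summarized per type, and the two sides are paired by curated label matching
(`align_datasets()`), with age-annotated pairs required to agree within
±2.5 days.

## Modeling scales

Six properties are strictly positive with right-skewed across-type
distributions (R~in~, Tau, AP~hw~, C~m~, Rheobase, FR~max~); all statistical
modeling of these happens on the log10 scale, with back-transformation for
reporting. Voltage-valued and dimensionless properties (V~rest~, AP~amp~,
AP~thr~, AHP~amp~, SFA) are modeled as-is. The registry is closed: no
operation accepts a property code outside the 11.

## Cross-study condition normalization

Article-level measurements of one property are modeled additively as

```
value ~ cell type + species + junction-potential status + electrode type
        + bs(log10(age), 5 df) + bs(temperature, 5 df)
```

fit with an elastic-net penalty (mixing weight 0.99, 100-value path) whose
strength is chosen by cross-validation with folds grouped by article — so a
duplicated article can never straddle folds — and stratified by cell type,
so every training fold retains (nearly) every type. The cell-type indicator
terms are included in the fit but left **unpenalized**: they are the
biology under study, and shrinking them lets genuine cell-type differences
leak into condition covariates they are partially confounded with (animal
age especially — a cell type's articles cluster around a typical age), which
the adjustment step would then wrongly remove. Measurements are then
adjusted to a reference condition using **only the non-cell-type terms**. Reference conditions default to the most frequent
level of each categorical term and the dataset median of log10(age) and
temperature; this choice is recorded in the serialized `condition_model` so
adjustments are reproducible.

Numerical choices worth knowing:

* Spline bases are cubic B-splines with 5 degrees of freedom (two interior
  knots at the observed tertiles); boundary knots are the observed covariate
  range, and prediction beyond them clamps to the boundary and flags the
  record rather than extrapolating a cubic.
* A covariate that is constant at fit time contributes no term; a
  categorical term with a single level is dropped with a warning.
* Condition models are fit on article-level records (the finer granularity)
  rather than on per-type summaries, and only afterwards are records
  summarized per cell type as the within-article mean followed by the
  across-article median.
* Junction-potential handling: records documented as corrected, with a
  known offset, have the correction reverted on the voltage-valued
  properties (V~rest~, AP~thr~) and are re-labeled `post_corrected`;
  amplitude-type properties are differences of voltages and carry no
  offset.

## The univariate screen

For every (gene, property) pair the screen computes the average-rank
Spearman correlation across the cell types where the property is observed
(pairwise-complete), with the two-sided p-value from the t approximation
`t = r sqrt((n-2)/(1-r^2))`. Benjamini–Hochberg adjustment is applied
**within property only**; no correction is made across properties, which are
themselves strongly inter-correlated. Genes with zero expression variance
over the complete cell types have no defined rank correlation; they are
excluded and logged rather than imputed as zero. Properties observed in
fewer than `min_celltypes_per_property` types (default 5 — a floor that
guards degenerate small simulations; real datasets sit far above it) are
skipped.

## Cross-dataset consistency and its permutation null

Two statistics compare a discovery screen against an independently
collected validation dataset:

* **Overall consistency** per property: the Spearman correlation between
  the two datasets' full r~s~ vectors over their common genes.
* **Per-gene consistency**: a pair discovered at FDR < 0.05 is *consistent*
  iff the validation correlation has the same sign and |r~s~| > 0.3; the
  summary is the percentage of discovered pairs that are consistent
  (non-evaluable genes stay in the denominator and are reported separately).

Both get permutation p-values by shuffling which validation ephys row is
paired with which validation expression row — each modality's internal
structure stays intact — and recomputing the statistic per shuffle
(default 1000). p-values use add-one smoothing, `p = (1 + #{null >=
observed}) / (B + 1)`, so a statistic beating every shuffle reports
1/1001 ≈ 0.001, conventionally printed "< 0.001". The test is one-sided
(greater), which is the direction in which consistency is meaningful: a
strongly negative overall correlation yields p near 1 rather than a second
significant tail.

## Sparse multivariate prediction

Each property is modeled from per-gene z-scored expression with a
**two-stage elastic net** (mixing 0.99): stage 1 runs the penalized fit
over the full gene panel with the penalty chosen by internal
cross-validation, and the genes with nonzero coefficients become the
selected set; stage 2 re-runs the same penalized procedure restricted to
the selected genes. The refit stays penalized because the selected set can
approach or exceed the number of cell types, where an unpenalized refit is
singular. The response is registry-transformed and standardized before
fitting, so coefficients live on a standardized scale and transfer across
differently normalized datasets.

Design choices in this stage:

* **Internal CV folds.** Penalty selection uses seeded 10-fold
  cross-validation. Leave-one-out penalty selection (available via
  `run_config(inner_nfolds = "loo")`) was considered as the default for
  small n, but the LOO curve for the penalty is itself high-variance and
  10-fold is the standard, better-behaved choice at these sizes.
* **Evaluation** is leave-one-out over cell types, with *everything* —
  per-gene scaling, response standardization, both fitting stages —
  recomputed inside each fold. R² is the unity-line form
  `1 − SSE/SST` over the pooled held-out predictions and can be negative.
* **Transfer** to an independently normalized dataset maps validation
  expression to log2(TPM+1) and z-scores per gene *within the validation
  dataset*; validation ephys is registry-transformed then z-scored within
  dataset. Because the two normalizations need not share an affine scale,
  the headline transfer metric is the squared Pearson correlation between
  predicted and observed standardized values; the stricter unity-line form
  is also reported. Whether y-standardization should precede or follow the
  log10 transform is not determined by the problem; the package transforms
  first, then standardizes.
* **Missing ephys** is handled per property: each model uses only the cell
  types where that property is observed; nothing is imputed across
  properties.
* **Bootstrap.** Performance variability is estimated by resampling
  expression samples within each cell type and ephys articles within each
  (cell type, property), both with replacement, then rebuilding the paired
  dataset through the standard summarization pipeline — stratification
  guarantees every cell type is present in every replicate. The bootstrap
  resamples the post-adjustment article-level records: it quantifies
  sampling variability given the fitted condition models, not uncertainty
  in the condition fit itself.

## The synthetic-data generator

Every statistical claim in the test suite is validated against data with
known ground truth from `generate_discovery_dataset()` /
`generate_validation_dataset()`. The generator emulates:

* per-cell-type replicate expression (log2) over a background floor of
  ~6 log2 units, with null genes' means pinned to that floor;
* planted monotone gene–ephys relationships: a planted gene's per-type mean
  is linear in the latent property value, with the slope calibrated —
  via the bivariate-normal identity r = 2 sin(πρ~s~/6) and a correction for
  replicate averaging — so the population Spearman magnitude of summarized
  expression against the latent hits the requested target;
* gene co-expression blocks driven by shared (centered) latent factors;
* article-level study effects added on the modeling scale: temperature
  slopes, log-age slopes, electrode and junction-potential offsets, species
  offsets, with metadata drawn per article; article ages scatter ~±35%
  around the cell type's typical age, reflecting that different labs
  characterize the same type at quite different ages (and keeping age
  identifiable separately from cell type);
* an scRNA-seq arm: per-line single cells whose TPM values exponentiate the
  same latent log2 signal, with dropout zeros at a configurable rate, and a
  disjoint set of per-cell ephys values around the same latent line means.

All randomness flows through named substreams of one seed, so the discovery
and validation arms of the same configuration share their latent state
exactly, and enlarging the gene panel does not perturb the ephys draws.

What the generator does **not** emulate: platform-specific noise spectra,
realistic gene names or annotation structure, non-monotone or combinatorial
gene–ephys relationships, and correlations *between* ephys properties
(latents are drawn independently per property). Passing tests therefore
demonstrate that the machinery recovers monotone planted structure under
additive study effects — not that real data satisfies those assumptions.

## Problem sizes used in validation

The test suite exercises the pipeline at sizes chosen to make the
statistical checks sharp while keeping the suite quick to run:
false-discovery control uses 50 global-null datasets of 2000 genes × 30
cell types; planted-effect recovery uses 10 datasets with 22 planted genes
each; condition-normalization recovery uses 50 datasets with a +0.5 mV/°C
planted temperature effect (slope shrinkage) and 50 with a fuller
lab-effect structure (accuracy improvement); permutation calibration uses
100 meta-replicates of 100 simulated null validation datasets (199
shuffles each) plus one 1000-shuffle run on shared-signal data — the null
validation expression carries a shared co-expression factor, because with
fully independent genes the consistency percentage is intrinsically
discrete and its permutation p conservative by construction, a property of
the statistic rather than of the implementation; predictive recovery uses
25 datasets with a 5-gene planted signal among 2000 genes at n = 30. The
acceptance script runs the full pipeline once at the generator's default
scale (34 types × 3000 genes, 12 validation lines) plus 10 global-null
screens.

## Known limitations

* Label pairing is an explicit curated mapping; no ontology or string
  matching is attempted, because real cell-type harmonization is semantic
  curation that cannot be automated faithfully.
* The condition model is additive; interactions between, say, temperature
  and cell type are not modeled, mirroring the additivity assumed by the
  adjustment step.
* Unit conversion is out of scope: inputs must already be in the registry's
  units (mV, MΩ, ms, pF, pA, Hz).
* The screen's t-approximate p-values are asymptotic; at very small n they
  are approximate, which is one reason the per-property minimum of 5 cell
  types exists.
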