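---
title: "Data-quality scoring, gap filling and screened nano-SAR models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-quality scoring, gap filling and screened nano-SAR models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`nanosar`, in the order the pipeline applies them, together with what the
synthetic-data generator does and does not emulate.

## The endpoint

Every record is one exposure observation: a nanomaterial, a cell line, an
assay, a dose (µg/mL), an exposure time (h) and a measured cell viability
(%). The classification endpoint is binary and strict: **Toxic** if and
only if viability < 50 %; a viability of exactly 50 % is Nontoxic.
Viability readouts above 100 % — common in colorimetric assays when
particles interfere with detection — are retained and labeled by the same
rule. The package treats each record as given; it does not aggregate
replicate readouts within a study, because curated tables rarely preserve
the information needed to do that defensibly.

## PChem data-quality scoring

Four physicochemical attributes are scored: core size (nm, TEM-class
methods), hydrodynamic size (nm, DLS/NTA), surface charge (mV, zeta
potential) and specific surface area (m²/g, BET). Each attribute receives

* a **data-source score**: 3 (authors' own experiment), 2 (manufacturer's
  specification), 1 (adapted from another reference on the same
  material), 0 (no data);
* a **method score**: 2 (the attribute's gold-standard technique),
  1 (other or estimated), 0 (no information).

The attribute total is their sum (0–5) and the record's final score is
the arithmetic mean over the four attributes, so 5 requires four
author-measured, gold-standard characterizations and 0 means no PChem
data at all. Scores are computed *before* any statistical imputation, and
mean-substituted values keep provenance "no data", so imputation never
inflates a score (`score_records()` accepts such tables).

Screening (`screen_by_score()`) sorts by final score descending and keeps
the top `floor(keep_fraction * n)` records, at least one. Ties at the
boundary are broken by `record_id`, a deliberate choice: "top 50 %" is
read as a count quantile, and a stable tie-break makes tier membership
reproducible across runs. The standard tiers are III-A (top 50 % of the
gap-filled data) and III-B (top 20 %).

## Gap filling

For each absent PChem value the first applicable rule wins:

1. **Manufacturer catalog** — same brand/product identifier; the filled
   value carries source level `manufacturer` (score 2) and the stated
   method, or `other` (score 1) when the catalog gives none. The
   conservative default avoids inflating method scores for vendor numbers
   of unknown origin.
2. **Reference catalog** — another publication on the same material;
   source level `reference` (score 1).
3. **Estimation** — core diameter and specific surface area are
   interconverted through the spherical-particle relation
   `SSA = 6/(d·ρ)`. With d in nm and ρ in g/cm³ the SI reduction fixes
   the constant: `SSA [m²/g] = 6000/(d·ρ)`. The estimate's method label is
   `estimated_from_core`/`estimated_from_ssa` (method score 1) and its
   source level is inherited from the basis value, since the scoring
   rules price estimation only on the method axis.

Absent quantum-mechanical (QM) descriptors (formation enthalpy,
conduction/valence band energies, electronegativity, all eV) are filled
by composition from a lookup table; a warning is raised for particles
below 5 nm, where bulk-like electronic properties are no longer
size-independent. Records that still contain gaps after all rules are
excluded from the gap-filled tier (II), and scores are recomputed — a fill
can only raise a source score from 0, so no surviving score drops.

Mean substitution (`mean_substitute()`, used for tier I at modeling time)
computes attribute means on the *training partition only* and applies them
to both partitions. The alternative — means over the whole table — leaks
test information into training; the package always takes the
leakage-free reading where the order of operations is otherwise open.

## Classification model and validation

The classifier is a random forest (500 trees, `mtry = floor(sqrt(p))` —
the conventional defaults of the algorithm family, since nothing else is
dictated by the problem), fit on z-normalized numeric attributes
(mean/SD from the training partition; constant columns are centered only)
and one-hot-encoded nominal attributes (assay, cell species, origin,
type). `cell_name` is carried in the schema but never modeled: with >50
levels it acts as a study identifier and would undermine generalization.
Dose and exposure time are numeric features; exposure time belongs to the
toxicological category in the importance studies, dose is its own
category.

Validation replicates a simple random 60/40 split five times
(replication *i* uses seed `base_seed + i`), evaluates on the held-out
40 % (external validation), optionally runs stratified 5-fold
cross-validation within the training partition, and averages the
unrounded metrics arithmetically. With Toxic as positive:
precision = TP/(TP+FP), sensitivity = TP/(TP+FN),
accuracy = (TP+TN)/n, F1 = harmonic mean of precision and sensitivity
(0 when both are 0). Undefined ratios are reported as 0 rather than NA so
that averages over replications remain defined; with a strongly
imbalanced endpoint F1 is the metric to watch, since accuracy is high
even for a majority-class predictor. Everything is seeded, so
`run_experiment()` is a pure function of its inputs.

## Applicability domain

For a training set, the per-sample statistic is the mean weighted
Euclidean distance to its k nearest neighbours (k = 5 by default; self
excluded; rank ties broken by sample index), computed on z-normalized
numeric attributes. The cutoff is `D_c = D̄ + Z·s` with `D̄` and `s` the
mean and SD of those statistics. Two readings of "distances to the other
samples" are possible — all pairwise distances, or kNN means; the kNN-mean
reading is implemented because it matches the k-nearest-neighbours
framing and is robust to the bulk of far-apart pairs. `Z` defaults to
1.645, the 95 % one-tailed normal quantile. Weights default to 1: after
z-normalization all attributes are on one scale, and no principled
attribute weighting is available a priori; they remain configurable.
Samples with statistic ≤ `D_c` form the retained subset, whose
per-attribute min/max (reported in original units, bounds inclusive)
define the numeric domain; nominal attributes contribute their observed
level sets. `in_domain()` checks both. Retained ranges are always
contained in the full-data ranges; across increasingly screened tiers
they *tend* to shrink — a predictivity/applicability trade-off — but
shrinkage is not an invariant attribute by attribute.

## Attribute importance

`loo_oob_importance()` removes one modeling attribute at a time, refits
the seeded forest on the replicated training partitions, and records the
out-of-bag error (1 − OOB accuracy, averaged over replications);
important attributes produce large errors when removed. The protocol is
blind to redundancy: removing one of two attributes that carry the same
information barely moves the error — the surface area/core size pair
linked by `SSA = 6000/(d·ρ)` is exactly such a case, and the test suite
checks that behavior rather than pretending it away.
`category_combination_study()` complements it at the category level:
dose is always kept, and combinations of the PChem, QM and Tox categories
are added in turn, each evaluated with the full replicated validation.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of a large
literature-curated corpus (defaults: 6,842 records, 26 oxide
compositions, one commercial product per composition on average):

* **Materials.** True core size lognormal (median 30 nm, clamped to
  6–400 nm), bulk density by composition, true SSA exactly `6000/(d·ρ)`,
  surface charge N(0, 22 mV), hydrodynamic size = core × agglomeration
  factor ≥ 1. Surface charge and hydrodynamic size get additional
  per-record session variation (6 mV; lognormal multiplier, sdlog 0.35)
  because both depend on the dispersion medium — they are record-level
  quantities, not exact material fingerprints.
* **Dose–response.** Viability follows a Hill curve
  `V = 100/(1 + (dose/EC50)^h)` with h = 1.2. log-EC50 = composition
  offset (SD 0.2) + 1.2·log(d/30) − 0.1·log(t/24): smaller particles and
  longer exposures are more toxic. A single global EC50 scale is
  calibrated — with the realized assay noise included — so the expected
  Toxic fraction equals the target (default 0.2, a clear Nontoxic
  majority; the real split is not published, so this is a free
  parameter). Doses come from a 4-point grid (2–200 µg/mL), times from
  6–72 h.
* **Study quality.** Each record draws a latent lognormal noise
  multiplier (sdlog 2.0). Its assay noise SD is 12 × multiplier
  (capped at 40 viability points); its per-attribute missingness odds
  increase with the multiplier (slope 2.5 on the log-odds scale, with
  intercepts calibrated by root-finding so the marginal rates equal the
  literature profile 18/39/41/74 % exactly in expectation); and its
  probability of using a gold-standard method decreases with it
  (baseline 0.6, slope 1.2). This single latent is what ties the
  observable quality markers (completeness, methods) to the unobservable
  one (label noise), and it is the mechanism by which score screening
  buys model performance. Plain attribute-wise MCAR missingness was
  rejected during development: with it, a random forest recovers material
  identity from the remaining low-noise columns and screening only costs
  sample size, so the quality→performance link the pipeline is meant to
  measure never materializes.
* **Provenance.** Observed values carry relative noise 3 % / 30 % / 60 %
  for experimental / manufacturer / reference sources (multiplicative for
  sizes and areas, additive for charge). Each material × attribute is
  assigned a recoverability stratum (15 % experimental-only, 45 %
  manufacturer, 25 % reference, 15 % unfillable), and the catalogs are
  emitted for exactly the recoverable strata — so tier II retains most
  records, as a gap-filling narrative requires.
* **Truth.** Noiseless values, per-record EC50, assay-noise SD and true
  labels are returned for oracle-style tests (e.g. with all noise and
  missingness switched off the observed table equals the truth, and
  Eq.-1 filling reconstructs the true SSA exactly).

What the generator does **not** emulate: per-article row clustering and
citation structure, dose–response curve fitting artifacts, correlated
multi-assay readouts of the same exposure, and real QM chemistry (its QM
table is synthetic constants, flagged as such). Passing the end-to-end
tests therefore demonstrates that the pipeline's machinery behaves as
designed under a plausible data-generating process — not that the same
F1 values would be obtained on any particular real corpus.

## Numerical and design notes

* Screening count: `floor(keep_fraction × n)`, minimum 1; ties by
  `record_id`.
* Score recomputation after filling is monotone non-decreasing per
  record (tested property).
* Normalization SD uses the n−1 denominator; SD = 0 → scale 1.
* Distances: ties in neighbour rank broken by sample index; the
  brute-force all-pairs oracle is cross-checked for n ≤ 50.
* All randomness flows from explicit seeds (`withr::with_seed`), so every
  result object is a pure function of (data, configuration).
* Test problem sizes: module tests use 120–4,000 synthetic records; the
  end-to-end tier-ordering check runs the full default configuration
  (n = 6,842, 500 trees, 5 replications), which completes in a few
  minutes on one core. Under reseeding of the generator the first two
  steps of the F1 ordering (I < II < III-A) are robust with wide margins,
  while the III-A → III-B step is a near-tie (III-B is five times
  smaller; its quality advantage and its sample-size penalty almost
  cancel) — consistent with treating the last steps as "≤" rather than
  strict improvements.

## Known limitations

* The scoring framework covers only the four PChem attributes; assay and
  cell-line quality are not scored.
* Gap filling groups materials by product identity only; no structural
  read-across or similarity grouping.
* No resampling for class imbalance (e.g. SMOTE) and no quantitative
  (regression) endpoint — both out of scope here.
* The applicability domain is range-based after a kNN distance filter;
  leverage- or density-based alternatives are not provided.
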