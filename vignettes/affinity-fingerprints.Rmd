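---
title: "Affinity fingerprints from conformal QSAR panels: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity fingerprints from conformal QSAR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qaffp)
```

# The model

An affinity fingerprint replaces a molecule's substructure vector with
its predicted bioactivity across a reference panel of assays. The
pipeline has four statistical layers, each with assumptions worth making
explicit.

## Per-assay regression

Each assay's ligand set (unique compounds, activities on the −log10
molar scale) is modelled by a random forest of 100 trees over 1024-bit
Morgan (radius 2) fingerprints. Following the bagging-of-full-trees
idiom for fingerprint QSAR, **every feature is eligible at every split**
(`mtry = p`); the randomness comes from the bootstrap alone. Bits that
are constant in the training data are dropped before fitting — they can
never split, so the model is unchanged while fitting gets much faster.
100 trees is enough for stable predictions at these set sizes; more
trees buy little.

The assumption doing the real work is that activity is a (locally
smooth) function of circular-substructure occurrence. Activity cliffs —
large activity changes from small structural edits — violate it, and
nothing in the pipeline can detect them.

## Validation gate

Model quality is judged by two complementary statistics:

* `q2`, the cross-validated fraction of activity variance explained,
  computed as the **mean of per-fold q² values** over all folds in all
  repeats (not the pooled-prediction variant). Folds are fixed by the
  split plan; repeats re-randomize only the forests, which are the
  stochastic component of bagged models.
* `r0Squared`, the coefficient of determination of test-set predictions
  under a regression **constrained through the origin** with slope
  k′ = Σyŷ/Σŷ². This punishes systematic scale distortion that ordinary
  R² forgives.

Admission requires q² ≥ 0.5 **and** R′₀² ≥ 0.6, both inclusive. The
split is activity-stratified: compounds are sorted by activity,
partitioned into consecutive blocks (of 5 for an 80:20 split; of k for
fold labels), and assignments are drawn at random within blocks. The
mechanics of "stratified sampling of continuous activities" are a
convention of this package; any scheme that matches the activity
distributions on both sides would do.

## Conformal applicability domain

A second forest (the *error model*) predicts the point model's absolute
residual; its output λ scales the nonconformity score α = |y − ŷ|/λ.
Three conventions matter:

* **Residual source.** Error-model targets are the point model's
  *out-of-bag* residuals on its own training compounds. In-sample
  residuals of a random forest are optimistically small and would
  shrink λ, inflating α and distorting calibration. Out-of-bag
  predictions provide out-of-fold residuals at zero extra cost. A
  consequence: even on noiseless data λ does not collapse to zero —
  it reflects the model's genuine out-of-sample error.
* **Floor.** λ is floored at 0.01 log units (configurable) so α is
  always defined.
* **Quantile.** The interval half-width is λ·α\* with α\* the
  ⌈(1 − ε)(n + 1)⌉-th smallest calibration score — the finite-sample
  correction that makes coverage ≥ 1 − ε exact under exchangeability.
  When the index exceeds n the interval is infinite: the calibration
  set is too small for that confidence.

With `method = "icp"` the training set is split into a proper training
set and a calibration set (default one third, activity-stratified), and
the *deployed* point/error models are the proper-training ones — this
keeps the conformal guarantee exact, at the price that the deployed
model sees fewer compounds than the gate-validated one. With
`method = "ccp"` all training compounds rotate through the calibration
role in k folds, the pooled scores form the table, and the deployed
models are refit on everything; the guarantee is then approximate.
Pooled scores (rather than per-fold interval aggregation) are this
package's documented choice for the cross-conformal variant.

A prediction is **in domain** when its interval width at the configured
confidence (default 0.90) does not exceed `maxWidth` (default 4.0, i.e.
± 2 log units).

## Fingerprints

`rvQaffp` emits raw point predictions per panel assay. With
`adPolicy = "impute"` an out-of-domain component is replaced by the
mean of that molecule's reliable components — the imputation is
**per molecule across assays**, because fingerprints must be computable
one molecule at a time; the per-assay reading of "mean of reliable
predictions" would require a reference population. `bQaffp` thresholds
at an activity cutoff (≥ cutoff → 1) and, under the recommended policy,
zeroes out-of-domain components: an unverifiable prediction is treated
as inactive, which reflects the base rates of screening data.
Recommended defaults throughout: rv — raw values, domain ignored;
b — cutoff 5, ICP domain at confidence 0.90, width 4.0.
`zStandardize` (population SD) is available for rv features used in
classifiers; it changes little in practice and is off by default.

# Benchmark harnesses

* **Similarity searching**: per repetition, query actives (10 for
  heterogeneous sets, a larger series for homogeneous ones) and a
  fraction of inactives (20% / 10%) are removed; the rest is ranked by
  MAX fusion over the queries. Binary affinity fingerprints are
  compared with the Rogot–Goldberg index — shared zeros (shared
  inactivity) are information, unlike in substructure bits — while the
  Morgan comparator uses Tanimoto, the convention for structural
  fingerprints. The homogeneous protocol's historical test-set cap
  ("99 actives") is platform lore, not a statistical necessity; the
  harness uses all held-out actives unless a cap is configured.
* **Classification**: balanced random forest (each tree bootstraps
  equal numbers from both classes, undersampling the majority; 100
  trees; GINI), stratified 5-fold cross-validation repeated 10 times,
  AUC and EF5 per fold. Sets must have strictly more than 60 compounds
  per class.
* **Scaffold hopping**: actives are compounds with activity strictly
  above 6; the cyclic skeleton (CSK) of the Bemis–Murcko scaffold
  defines the chemotype. Every *rich* active CSK (≥ 5 actives) seeds a
  training set (its actives + all inactives); the classifier's hits
  among the remaining actives contribute their CSKs to the retrieved
  union. Pooling two schemes' results is a set union.

Tie handling: AUC uses the Mann–Whitney ½-credit convention; the EF5
top segment is N<sub>χ</sub> = ⌈χN⌉ with boundary ties broken by a
seeded pre-shuffle so EF never depends on input order. Scheme
comparisons use the exact paired Wilcoxon signed-rank test, computed by
a convolution equivalent to enumerating all 2ⁿ sign assignments (exact
under midranks/ties, capped at n = 25); confidence intervals are
Hodges–Lehmann order statistics of Walsh averages at exact signed-rank
critical values.

# The synthetic-data generator

Real activity data cannot ship with the package, so every stage is
exercised against a generator with known ground truth:

* **Molecules** come from a deterministic fragment grammar: eight ring
  cores (six distinct cyclic skeletons) × up to two acyclic
  substituents from a fixed list of 25 — about 2600 valid, canonical,
  ring-bearing SMILES. Validity and scaffold-family membership are
  guaranteed by construction, which random SMILES strings cannot offer.
* **Assays** (`generateLigandSet`): activity = offset + Xw + N(0, σ)
  over `nSignalBits = 12` informative fingerprint bits (library
  prevalence 10–90%) with weights of magnitude 0.3–1.0 and random
  sign, clipped to [3, 11] to mimic realistic potency ranges and keep
  the 5–8 cutoffs meaningful. A 12-bit signal of this size is what a
  clean, strong structure–activity relationship looks like to a
  fingerprint model; at σ = 0 the gate should and does recover it.
* **CLASS sets** (`generateClassSet`): actives drawn from several
  distinct-CSK families (the first always ≥ 5 members, guaranteeing a
  rich scaffold), activity signal planted through substituent choice
  so it generalizes across scaffolds, actives at 6.2–9.0 and inactives
  at 3.2–4.8 — the ≤ 5 / ≥ 6 labelling rule with an empty gap, as in
  curated classification sets.

What the generator does **not** emulate: real medicinal-chemistry
property distributions, assay-specific noise structure,
property-matched decoys, activity cliffs, or inter-assay correlation.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under its stated assumptions — not that any particular
real-data benchmark value would be reproduced.

# Problem sizes and numerical choices

Simulation-backed checks in this package run at desk scale, chosen so
the full suite completes in minutes on one core: conformal validity
uses ~2600 compounds (400 proper-training; the rest repeatedly divided
into ~200 calibration and 2000 test compounds, with coverage averaged
over the role assignments because the conformal guarantee bounds
*expected* coverage and a single 200-compound calibration draw measures
it with about two percentage points of sampling noise);
gating-recovery sweeps use 20 seeds × 200 compounds with 10-fold
cross-validation and 2 repeats (at σ = 0 the q² estimate is insensitive
to the repeat count); the end-to-end pipeline check builds a 20-assay
panel with 5-fold, single-repeat validation. Degenerate inputs are
errors, not silent results: constant observed activities (undefined q²),
all-zero predictions (undefined k′), all-zero paired differences,
single-class AUC. Constant fingerprint columns are dropped per model;
an entirely constant feature matrix is an error. Molecule identity is
OpenBabel canonical SMILES everywhere; equality of cyclic skeletons is
string equality of their canonical SMILES.

Two scaffold conventions deserve a note, since the underlying
definitions are genuinely open. The Bemis–Murcko extractor keeps atoms
attached to the framework by double/triple bonds (ring carbonyl oxygens
stay; whole side chains, including their carbonyls, are pruned). The
CSK, however, is reduced to the ring-and-linker core *after* bond
flattening: retained exocyclic atoms become single-bonded terminal
atoms, which the all-single-bond skeleton would prune anyway — reducing
first keeps the operation idempotent, which the retrieval counting
relies on.

# Known limitations

* Panels built from synthetic data inherit the generator's simplicity;
  real panels need real curated activity tables in the documented
  format.
* The ICP deployed model is trained on two thirds of the training
  compounds; for very small ligand sets the cross-conformal variant
  uses data more efficiently at the cost of an approximate guarantee.
* Affinity fingerprints are derived from structural fingerprints, so
  they cannot surface activity relationships invisible to the
  underlying Morgan representation.
* The exact Wilcoxon machinery stops at 25 pairs; larger comparisons
  need a normal approximation, which the package deliberately does not
  silently substitute.
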