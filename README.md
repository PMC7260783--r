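# qaffp: QSAR-derived affinity fingerprints with conformal applicability domains

Structural fingerprints describe what a molecule *is*; affinity
fingerprints describe what it *does*. `qaffp` builds the in-silico
variant: a panel of per-assay QSAR regression models predicts a
molecule's activity across hundreds of protein-target assays, and the
vector of predictions becomes the molecule's descriptor. Because every
component is a model prediction, each one carries a conformal
applicability-domain flag saying whether it should be trusted. The
package is aimed at cheminformaticians doing ligand-based virtual
screening, bioactivity classification and scaffold hopping who want a
bioactivity-space descriptor built entirely from public-style activity
data.

## The method

For each assay (one organism/target/activity-type combination) with more
than 50 curated activity records (relation `=`, types IC50/EC50/Ki/Kd,
high curation confidence, replicates averaged only when their SD < 0.5
log units):

1. **Point model.** A random forest (100 trees, all features eligible at
   every split) regresses activity (−log10 M) on 1024-bit Morgan
   (radius-2) fingerprints, using an activity-stratified 80:20
   train/test split.
2. **Gate.** The model enters the panel only if the repeated ten-fold
   cross-validated q² ≥ 0.5 **and** the test-set through-origin
   R′₀² ≥ 0.6, where

   q² = 1 − Σ(yᵢ − ŷᵢ)² / Σ(yᵢ − ȳ)²,  R′₀² = 1 − Σ(yᵢ − k′ŷᵢ)² / Σ(yᵢ − ȳ)²,
   k′ = Σyᵢŷᵢ / Σŷᵢ².

3. **Conformal wrap.** A second forest predicts the point model's
   absolute residual; the scaled nonconformity score α = |y − ŷ|/λ is
   calibrated on held-out compounds (inductive conformal prediction, or
   a k-fold cross-conformal variant). At confidence 1 − ε the interval
   half-width is λ·α\*, with α\* the ⌈(1 − ε)(n + 1)⌉-th smallest
   calibration score. A prediction is *in domain* when the interval
   width stays below 4.0 log units.
4. **Fingerprints.** The real-valued fingerprint (`rvQaffp`) is the
   vector of point predictions across the gated panel; the binary form
   (`bQaffp`) thresholds each component at an activity cutoff (default
   5, i.e. 10 µM) and zeroes out-of-domain components (an unreliable
   prediction is treated as inactive).

Evaluation harnesses reproduce the standard protocols: similarity
searching with MAX group fusion (Rogot–Goldberg similarity for binary
affinity bits, Tanimoto for Morgan bits), balanced random forest
classification under repeated 5-fold cross-validation, scaffold hopping
over Bemis–Murcko cyclic skeletons (CSKs), with AUC/EF5 scoring and
exact paired Wilcoxon comparisons between schemes.

## Worked example

```r
library(qaffp)

# synthetic activity data with planted structure-activity signal
tab <- generateActivityTable(nAssays = 3, nCompounds = 110,
                             noiseSigma = 0.1, seed = 7)
cfg <- qaffpConfig(seed = 7, cvFolds = 5, cvRepeats = 1)
panel <- runBuild(tab, "panel-demo", cfg)
#> curation: 366 records -> 348 after filters -> 330 compound-assay pairs -> 3 ligand sets
#> assay ASSAY-001: n = 110, q2 = 0.571, R'0^2 = 0.646 -> pass
#> assay ASSAY-002: n = 110, q2 = 0.775, R'0^2 = 0.839 -> pass
#> assay ASSAY-003: n = 110, q2 = 0.553, R'0^2 = 0.768 -> pass

# fingerprints for new molecules
mols <- parseMolecules(c("CCOc1ccccc1C(=O)N", "c1ccc2ccccc2c1"))
bQaffp(panel, mols, cutoff = 5)
#> BitFingerprint: 2 molecules x 3 assays; cutoff 5 (AD-zeroed); density 0.667
round(rvQaffp(panel, mols)@values, 2)
#>                   ASSAY-001 ASSAY-002 ASSAY-003
#> CCOc1ccccc1C(=O)N      6.61      6.31      5.61
#> c1ccc2c(c1)cccc2       6.83      5.95      6.28
```

The build log reads: 366 raw records survive the relation/confidence
filters as 348, aggregate to 330 unique compound-assay pairs, and form
3 ligand sets; all three models clear the q² ≥ 0.5 / R′₀² ≥ 0.6 gate, so
the panel has 3 positions. The rv fingerprint rows are each molecule's
predicted activities (−log10 M) across those assays; with cutoff 5 and
domain zeroing, four of six components binarize to 1 (density 0.667).
`cyclicSkeleton("c1ccncc1")` returns the pyridine skeleton `C1CCCCC1`;
`potencyFromConcentration(10, "uM")` is exactly 5.

## Layout

- `R/` — parsing/fingerprints/scaffolds (`chemstruct`), record curation,
  QSAR gating, conformal machinery, panel + fingerprint emission, metric
  kernel and benchmark harnesses, synthetic-data generator, pipeline.
- `inst/cli/qaffp.R` — `Rscript` dispatcher (`synth`, `curate`, `build`,
  `fingerprint`, `bench`).
- `vignettes/affinity-fingerprints.Rmd` — the methods vignette: model
  assumptions, parameter meanings, numerical conventions, limitations.
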