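# cesmrad

First-order radiomics and discriminant classification for
contrast-enhanced spectral mammography (CESM).

CESM produces two paired views of a breast lesion: a **low-energy (LE)**
image, equivalent to a standard digital mammogram, and a **recombined
(RC)** subtraction image that highlights iodinated-contrast uptake and
hence tumor neo-angiogenesis. `cesmrad` asks how much the gray-level
statistics of a lesion's region of interest (ROI) on these two images
tell us about the lesion's histology, and answers it with a complete,
reproducible pipeline:

* **Feature extraction** — seven first-order statistics per image, 14
  per lesion: mean; variation coefficient VC = σ/μ; gray-level range
  (max − min); skewness m₃/σ³; histogram entropy −Σ pᵢ log₂ pᵢ over 256
  equal-width bins; relative smoothness 1 − 1/(1 + σ²norm); kurtosis
  m₄/σ⁴.
* **Association testing** — Pearson correlation of every feature with
  ER%, PR% and Ki67%; Mann–Whitney tests (exact for small untied
  samples, tie-corrected normal otherwise) against HER2 and grade
  (G3 vs G1–G2); Bonferroni adjustment per outcome family.
* **Classification** — six binary tasks (ER ≥ 1%, PR ≥ 20%,
  Ki67 ≥ 20%, G3 vs G1–G2, triple-negative, HER2) with closed-form
  pooled-covariance LDA, δ₊(x) − δ₋(x) scores under leave-one-out
  cross-validation, and threshold-swept ROC curves whose trapezoidal
  AUC equals the Mann–Whitney pairwise identity exactly.
* **Synthetic cohorts** — a self-contained generator (labels + LE/RC
  images + masks) with known, configurable feature–label effects, so
  every stage is testable without patient data, plus exact raster
  round-trip I/O (16-bit TIFF images, PNG masks, CSV labels, JSON
  manifest).

The core data objects are Bioconductor-style S4: `CesmImagePair`,
`CesmCohort`, and `RadiomicFeatureSet` (a `SummarizedExperiment` of
the 14 × n feature matrix with histology labels in `colData`).

## Worked example

Generate a 68-lesion synthetic cohort with two planted effects — a
Pearson correlation of 0.35 between Ki67% and the RC variation
coefficient, and a standardized mean difference of 1.2 on the RC mean
between HER2+ and HER2− lesions — then run the full analysis:

```r
library(cesmrad)

cfg <- cohortConfig(nLesions = 68, seed = 1,
    effectMap = data.frame(
        label   = c("ki67_pct", "her2"),
        feature = c("RC_VC",    "RC_Mean"),
        effect  = c(0.35,       1.2)))
coh <- generateCohort(cfg)
coh
#> CesmCohort with 68 lesions
#>   images: 64x64 LE/RC pairs
#>   ER+ (>=1%): 58 | PR+ (>=20%): 28 | Ki67+ (>=20%): 41 | HER2+: 19 | G3: 24

fs  <- extractFeatures(coh)          # RadiomicFeatureSet, 14 x 68
tab <- associationTable(fs)
as.data.frame(tab)[tab$outcome == "Ki67" & tab$feature == "RC_VC", ]
#>    outcome feature statistic_type statistic n_used       p_raw family_size
#> 37    Ki67   RC_VC      pearson_r  0.360749     68 0.002510023          14
#>    p_adjusted
#> 37 0.03514032

taskSummary(runAllTasks(fs))
#>        task n_pos n_neg auc_pct note
#> ER       ER    58    10   28.62
#> PR       PR    28    40   48.93
#> Ki67   Ki67    41    27   55.01
#> Grade Grade    24    44   59.19
#> TN       TN     6    62   47.58
#> HER2   HER2    19    49   78.20
```

Reading the output: the planted Ki67↔RC_VC effect is recovered at
r = 0.36 and survives the per-outcome Bonferroni correction
(p_adjusted = 0.035); the planted HER2 enhancement-mean shift yields a
cross-validated AUC of 78% while the unplanted tasks hover around
chance (LOO AUCs on null 68-lesion cohorts scatter around and below
50%). `runPipeline(pipelineConfig(...))` runs the same stages and
writes `features.csv`, `associations.csv`/`.md`, `task_summary.csv`,
per-lesion LOO scores, a ROC overlay figure, the resolved config and a
log — byte-identical across reruns with the same seed. A thin CLI
(`inst/scripts/cesm-pipeline.R`) exposes `generate`, `extract`,
`associate`, `classify` and `run` subcommands.

See the vignette (`vignettes/cesmrad-methods.Rmd`) for the texture
model behind the generator, the effect-calibration procedure, and the
package's numerical conventions.

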