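---
title: "First-order CESM radiomics with cesmrad: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order CESM radiomics with cesmrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesmrad)
```

## The problem

Contrast-enhanced spectral mammography (CESM) produces, per view, a
low-energy (LE) image — essentially a standard digital mammogram — and a
recombined (RC) image obtained by subtracting low- and high-energy
acquisitions, which highlights iodine uptake and hence tumor
neo-angiogenesis. A natural question is whether simple gray-level
statistics of a lesion's region of interest (ROI) on these two images
carry information about the lesion's histology: hormone-receptor
expression (ER%, PR%), proliferative activity (Ki67%), HER2 status,
histological grade, and the triple-negative phenotype.

`cesmrad` implements that analysis end to end:

1. seven first-order features per image (14 per lesion),
2. feature–histology association testing with Bonferroni control,
3. six binary classification tasks via pooled-covariance linear
   discriminant analysis (LDA) under leave-one-out (LOO)
   cross-validation, summarized by ROC/AUC,
4. a fully synthetic cohort generator with *known, configurable*
   feature–label structure, so every stage is testable without access
   to patient images.

## First-order features

For ROI pixel values $x_1,\dots,x_n$ with mean $\mu$ and population
standard deviation $\sigma$ the package computes:

| Feature | Definition |
|---|---|
| Mean | $\mu$ |
| VC | $\sigma/\mu$ (variation coefficient) |
| Max-Min | $\max x - \min x$ |
| Skewness | $m_3/\sigma^3$ |
| Entropy | $-\sum_i p_i \log_2 p_i$ over 256 equal-width bins on $[\min x, \max x]$ |
| RelativeSmoothness | $1 - 1/(1+\sigma_{\text{norm}}^2)$ |
| Kurtosis | $m_4/\sigma^4$ (non-excess) |

where $m_k$ is the $k$-th central population moment and
$\sigma_{\text{norm}}$ is $\sigma$ after linearly rescaling the
*representable* intensity range (e.g. $[0, 65535]$ for 16-bit data) to
$[0,1]$. Normalizing relative smoothness by the representable range
rather than the ROI's own range keeps the feature comparable across
lesions. These are the standard first-order definitions
(Gonzalez–Woods relative smoothness, population moments, bits for
entropy); each convention is switchable (`sampleMoments`,
`excessKurtosis`, `logBase`, `nBins`) because first-order feature
definitions vary across the radiomics literature.

Degenerate inputs are flagged rather than silently propagated: VC is
`NA` when $|\mu|$ falls below $10^{-9}$ of the representable range
(RC images have near-zero backgrounds, and an unlucky ROI mean close
to zero would otherwise produce a huge, meaningless VC that dominates
the discriminant); skewness and kurtosis are `NA` at zero variance;
entropy of a constant ROI is 0 by convention. Lesions with `NA`
features are excluded pairwise from association tests (with `n_used`
reported) and dropped, with a message, from classification.

## Association testing

Each of the 14 features is tested against ER%, PR% and Ki67% with the
Pearson correlation ($t$-transform p-value, pairwise-complete
observations) and against HER2 (+/−) and grade with the Mann–Whitney
test. Grade enters as the binary split G3 versus G1∪G2 — the same split
the high-/low-grade classification task uses; the Mann–Whitney test
requires two groups, and the clinically meaningful boundary is at G3.

The Mann–Whitney implementation enumerates the exact permutation null
for small untied samples (default cap: 25 total observations) and
otherwise uses the tie-corrected normal approximation with continuity
correction. Exactness is verified in the test suite against full
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings for every
$n_1, n_2 \le 8$.

Bonferroni families default to *per outcome* (14 tests each): the
association table is organized per outcome row, and per-outcome
families are the weakest multiplicity assumption consistent with
starring rows independently. A single global family (70 tests) is
available via `family = "global"`.

## Classification

The six tasks binarize histology as: ER+ iff ER ≥ 1%, PR+ iff
PR ≥ 20%, Ki67+ iff Ki67 ≥ 20%, Grade+ iff G3, HER2+ iff HER2 positive,
TN iff ER−, PR− *and* HER2−. Cutoffs sit on the positive side
(ER = 1% is positive), matching the clinical ER ≥ 1% convention. The
triple-negative rule includes HER2 negativity — the standard clinical
definition — even though "non-triple-negative" is sometimes loosely
described via hormonal receptors alone.

LDA is fit from its closed form: class means $\mu_\pm$, pooled
within-class covariance $\Sigma$ (divisor $n-2$) plus a ridge
$\lambda I$, priors $\pi_\pm$ from class proportions, and the score
$$ s(x) = \delta_+(x) - \delta_-(x)
   = x^\top \Sigma^{-1}(\mu_+-\mu_-)
   - \tfrac12 (\mu_++\mu_-)^\top \Sigma^{-1}(\mu_+-\mu_-)
   + \log(\pi_+/\pi_-), $$
whose logistic transform is exactly the Gaussian posterior. The
default ridge, $10^{-6}\,\mathrm{tr}(\Sigma)/p$, only guards against
numerically singular covariances; at 14 features and 67-lesion
training folds it changes nothing detectable. LOO refits the model $n$
times; the ROC is swept over all unique thresholds of the pooled LOO
scores (ties advance the curve diagonally, making the trapezoidal AUC
equal the Mann–Whitney pairwise identity exactly), which is the
standard way to summarize LOO scores with a single curve.

Two numerical facts worth recording:

* **Standardization.** Whether features are standardized before LDA is
  immaterial *for the unregularized fit*: LDA is affine-equivariant, so
  any fixed (or fold-wise) affine rescaling reproduces the same scores
  up to a monotone map and the same AUC. The `standardize` flag
  computes means/sds inside each training fold — the only correct
  placement in general — and the suite verifies it leaves the AUC
  unchanged, i.e. there is no leakage channel to guard here. With a
  ridge the scale does interact (the penalty is isotropic), which is
  why the flag exists at all.
* **Reference agreement.** The closed form reproduces per-fold
  `MASS::lda` + `predict` posteriors to $10^{-15}$. (`MASS`'s `CV = TRUE`
  shortcut is *not* an exact refit oracle — it applies a
  degrees-of-freedom-adjusted predictive rule that differs from plain
  plug-in refits by up to ~0.01 in posterior at $n = 40$.)

A task is reported infeasible, without affecting the others, when its
smaller class has fewer than 2 usable lesions; with exactly 2, each LOO
fold still contains at least one member of each class and the pooled
covariance remains defined.

## The synthetic cohort generator

No public CESM lesion archive with paired LE/RC ROIs and full
receptor tables exists, so the package ships a generator whose
defaults emulate a realistic malignant cohort of 68 lesions: ER+
(≥ 1%) in 58/68, PR+ (≥ 20%) in 33/68, Ki67+ (≥ 20%) in 47/68, HER2+
in 16/68, grades G1/G2/G3 at 14/28/26. Receptor percentages follow
piecewise power-law marginals joined by a Gaussian copula; ER and PR
are coupled at 0.6 (their strong clinical co-expression), which also
lifts the triple-negative fraction toward the ~10% seen clinically
(independence would give ~6%). HER2 and grade are independent of the
rest by default — the joint dependence of real receptor panels is only
partially known, and the copula block is the single place to extend it.

Images are statistical phantoms, not anatomy: a Gaussian background
(label-independent by construction) and a disc ROI whose pixels follow
a skew-normal field parameterized by exact mean $\xi$, standard
deviation $\omega$ and shape $\alpha$. The RC background is centered
at zero so subtraction-style negative pixels occur and are preserved
end to end. Four per-lesion latents per image drive the field:

* location → Mean,
* scale → VC, Max-Min, RelativeSmoothness,
* shape (asymmetry) → Skewness, Kurtosis,
* gray-level granularity → Entropy.

The granularity latent — a per-lesion quantization step applied to the
ROI texture — deserves explanation. Histogram entropy over equal-width
bins spanning the ROI's *own* range is exactly scale-invariant, so the
field's standard deviation cannot move it (we measured a
feature–latent correlation of 0.00 at $n = 4\times10^4$); a texture
model that wants to plant entropy effects needs a knob that changes
the *occupied fraction* of the histogram support. Quantizing the
texture to a step $q$ does precisely that (occupied bins
$\approx \text{range}/q$), emulating differences in effective
gray-level granularity of detector/post-processing chains. A side
effect is that entropy becomes positively coupled to the scale latent
(occupied bins scale with $\sigma/q$), so variability and entropy
features associate together — the pattern real CESM cohorts show.

Planted effects are specified in feature space — a Pearson correlation
for continuous labels, a standardized mean difference (converted
internally through the point-biserial identity) for HER2/grade — and
realized on the latents after dividing by per-feature calibration
constants (`inst/scripts/calibrate_effects.R`; stored in the package
source). The constants are the measured feature–latent correlations
under default settings (ROI of ~1000 pixels): ≈ 0.99 for Mean/VC,
0.95 for Max-Min, 0.92 for skewness, 0.77 for entropy, 0.58 for
kurtosis — the attenuation is almost entirely finite-ROI sampling
noise. Feasibility is checked up front: a target needing a latent
loading ≥ 1, two features claiming the same latent, or joint loadings
whose quadratic form exceeds 1 are rejected with the offending triple
named.

Reproducibility uses one L'Ecuyer-CMRG root stream (labels) plus one
child stream per lesion (`parallel::nextRNGStream`), so cohorts are
byte-identical for a given (config, seed) and stable under lesion
reordering; the caller's RNG state is restored on exit.

**What the generator does not emulate.** Anatomy, dual-energy physics,
contrast kinetics, spatial texture (pixels are exchangeable within the
ROI — there is deliberately no spatial autocorrelation, since
first-order features cannot see it), multifocality (one lesion per
synthetic patient), ROI mis-segmentation, and scanner batch effects.
Passing tests on these cohorts therefore demonstrate *computational*
correctness — that the pipeline measures what it claims, controls its
error rates on null data, and recovers effects of known size — not that
any particular clinical effect size is achievable on real images. Two
further caveats: planting the *same* label on two features whose
pathways interact (e.g. RC Mean and RC VC, since VC = σ/μ responds to
the location latent too) realizes partially cancelled joint effects —
single-feature targets are accurate to the stated ±0.05, joint ones are
qualitative; and the calibration constants are estimated for the
default geometry and noise scale, so planted magnitudes drift if those
are changed substantially (re-run the calibration script in that case).

## Numerical and design choices

* Entropy bins: 256 equal-width bins over the ROI's own range — the
  most common first-order radiomics convention; configurable.
* Disc masks are rasterized by per-pixel center test; masks are
  rasters, not polygons, making the feature definitions unambiguous.
  Rasters of fewer than 16 foreground pixels are rejected (unstable
  third/fourth moments).
* On-disk format: 16-bit TIFF for LE/RC (RC with a +32768 integer
  offset recorded in the manifest, so negatives round-trip exactly),
  8-bit 0/255 PNG masks, CSV labels, JSON manifest. Integer pixel
  round-trips are exact by test.
* Pearson p-values via the exact $t$ transform; exact Mann–Whitney
  only without ties (ties fall back, with a warning, to the corrected
  normal approximation).
* LOO at $n$ lesions is lesion-level, matching a pooled multi-lesion
  analysis; patient-grouped CV is a natural extension and the reason
  `patient_id` exists separately from `lesion_id`.

## Problem sizes used by the checks

The shipped verification suite runs the feature oracle on 100 random
ROIs (16–4096 pixels), enumerates exact Mann–Whitney nulls up to
8 + 8, calibrates the null behavior on 200 replicate 68-lesion
cohorts (family-wise error of each outcome within binomial 99% bounds
of 0.05; ≥ 95% of LOO AUCs below 0.75 per task), recovers a planted
Ki67↔RC_VC correlation of 0.5 within ±0.05 at $n = 2000$, and checks
the Gaussian benchmark — LOO AUC $\to \Phi(D/\sqrt2)$ at Mahalanobis
distance $D \in \{0.5, 1, 2\}$ — within ±0.02 at $n = 4000$. These
sizes make the whole suite run in a few minutes while keeping every
Monte-Carlo tolerance well above its sampling noise.

## A worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(
    synthetic = cohortConfig(
        nLesions = 68, seed = 1,
        effectMap = data.frame(
            label   = c("ki67_pct", "her2"),
            feature = c("RC_VC",    "RC_Mean"),
            effect  = c(0.35,       1.2))),
    outputDir = "cesm-demo")
res <- runPipeline(cfg)
taskSummary(res$results)
print(formatAssociationTable(res$associations))
```

The same run is available from a shell via
`inst/scripts/cesm-pipeline.R run --synthetic --n 68 --seed 1`.
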