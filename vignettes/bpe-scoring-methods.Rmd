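---
title: "Automated BPE scoring for breast DCE-MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated BPE scoring for breast DCE-MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpescore)
```

## The problem

Background parenchymal enhancement (BPE) is the contrast uptake of normal
fibroglandular tissue (FGT) on dynamic contrast-enhanced breast MRI. It is
clinically rated on the ordinal BI-RADS scale — minimal, mild, moderate,
marked — by visual inspection of early post-contrast images, and it matters
because higher BPE is associated with elevated breast cancer risk. Visual
rating has two well-known weaknesses: inter- and intra-reader variability,
and inflation by the enhancement of a tumor, whose angiogenesis-driven signal
can be mistaken for parenchymal background.

`bpescore` implements an automated scoring pipeline that addresses both: it
derives a scalar computer BPE score from projection images of subtraction
volumes, and it *electronically removes* the known lesion before scoring so
the lesion cannot inflate the estimate. The package also ships a synthetic
phantom generator so that every stage can be trained, exercised and verified
without any clinical data.

## Pipeline overview

For one exam (pre-contrast volume plus at least two post-contrast volumes on
a shared grid):

1. **Subtraction** (`subtract`): post-contrast minus pre-contrast, clipped at
   zero by default. Clipping does not affect maximum-intensity projections
   and keeps average projections from being pulled down by noise; it can be
   disabled (`clip_negative = FALSE`).
2. **Lesion segmentation** (`segment_lesion`): fuzzy c-means (FCM) clustering
   of the subtraction intensities inside a user-supplied rectangular ROI
   around the diagnosed lesion. The cluster with the highest center is the
   lesion class; voxels with membership above 0.5 are candidates, the largest
   26-connected component is kept, and holes are filled slice by slice.
   The lesion size is reported as the square root of the lesion area on the
   center lesion slice (the slice of maximal area, ties to the lower index).
3. **Electronic lesion removal** (`remove_lesion`): on each slice through the
   lesion, lesion pixels are replaced by one constant — the mean intensity of
   the pixels bordering the slice's lesion region (a 1-pixel, 8-connected
   dilation ring by default). No blending or texture synthesis: the fill is
   deliberately the simplest faithful operation. If a lesion fills an entire
   slice the fill falls back to the 3D border mean, with a warning.
4. **Projection** (`project`): per-pixel maximum (MIP) or arithmetic mean
   (AIP) over the slice axis.
5. **Breast masks** (`train_segmenter`, `predict_probability`,
   `postprocess_mask`, `split_breasts`): a small U-Net maps a second
   post-contrast subtraction MIP to a breast probability map; a threshold of
   0.25 binarizes it, the largest 8-connected object (holes filled) is the
   region containing both breasts, and a vertical split at the horizontal
   center of its bounding box yields affected and unaffected breast masks.
6. **Scoring** (`score_grid`, `compute_score`): the projection is quantized
   to 8-bit display intensities and the computer BPE score is the mean pixel
   intensity within a breast mask, emitted for the full variant grid
   {both, affected, unaffected} x {MIP, AIP} x {first, second post-contrast}
   x {original, rescaled} x {with, without lesion removal}.
7. **Evaluation** (`kendall_tau_b`, `dichotomize`, `roc_analysis`,
   `ratio_vs_size_table`, `evaluate_cohort`): Kendall tau-b rank correlation
   of scores against ordinal ratings with a tie-corrected normal-approximation
   significance test; empirical ROC analysis (Mann-Whitney AUC, DeLong
   standard error, two-sided z-test against AUC = 0.5 with optional
   Bonferroni correction) for the minimal-vs-marked and low-vs-high
   classification tasks; and the after/before score-ratio summary by lesion
   size.

`run_exam` and `run_cohort` orchestrate the stages; one corrupt exam is
reported and skipped, never fatal for a cohort.

## The fuzzy c-means step

`fcm_cluster` is the standard alternating scheme on 1D intensities:
memberships $u_{ik} \propto d_{ik}^{-2/(m-1)}$ row-normalized, centers
$v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m$, iterated until the largest
center shift falls below `tol` (default `1e-5`, cap 300 iterations). The
fuzzified objective $J = \sum_{ik} u_{ik}^m d_{ik}^2$ is non-increasing,
which the tests assert on every run. Initialization is deterministic
(centers equally spaced over the data range); random initialization is
available and seeded.

Two parameters deserve comment:

* **Fuzziness `m = 2`** is the canonical choice and is exposed.
* **Cluster count: `segment_lesion` defaults to `c = 3`**, not 2. A lesion
  ROI on a subtraction volume typically contains three intensity
  populations — background/fat, enhancing parenchyma, and the
  hyper-enhancing lesion. With `c = 2` the bright cluster merges the lesion
  with enhancing FGT whenever the box overlaps parenchyma, and the
  largest-component step then returns the union (we measured Dice dropping
  from 1.0 to 0.32 on a 10 mm phantom lesion for exactly this reason). With
  `c = 3` the highest-center class isolates the lesion across all phantom
  levels and diameters we generate. `fcm_cluster` itself keeps `c = 2` as
  its generic default; the pipeline sets 3.

The ROI is an input, not a detection result: the method assumes a diagnosed
lesion with a known approximate location, and lesion *detection* is out of
scope.

## The U-Net breast segmenter

The segmenter is a compact 2D encoder–decoder with skip connections: two 3x3
convolutions + ReLU per level, 2x2 max pooling, nearest-neighbor upsampling,
a 1x1 output convolution and a sigmoid, trained with Adam (learning rate
`1e-3`) on a pixel-wise binary cross-entropy loss. Default geometry is 3
levels with base width 8 at a 128 x 128 input, chosen because the breast
outline on a projection image is a large, stereotyped, high-contrast shape:
at desk scale this trains in minutes on a single CPU and reaches held-out
Dice above 0.98 on phantoms, and both depth and width are arguments for
anyone who needs more capacity. Convolutions are evaluated as im2col gathers
followed by BLAS matrix products, and the whole training loop is
deterministic given its seed. Model artifacts serialize to plain JSON
(`save_segmenter` / `load_segmenter`).

A non-learned fallback (`fallback_segmenter`: Gaussian blur, log
compression, 3-class 1D intensity clustering with quantile-initialized
k-means keeping the two brightest classes) lets the pipeline run without any
training step. It is *not* the U-Net pathway and is labeled as such; it
exists so `run_cohort` works out of the box.

Training masks — and the phantom truth masks — exclude the chest wall, so
the network learns to exclude it too.

## Scoring: quantization and the two intensity modes

The score operates on 8-bit display-style images ("pixel values 0 to 255").
Two design questions are genuinely open in this kind of pipeline and we made
the following choices:

* **Quantization window.** We map subtraction intensities to 0..255 with a
  *fixed* window (`window_max = 255`, values above it clip), i.e. one
  intensity unit means the same thing in every exam, as it would on
  identically windowed display images. The alternative — windowing each
  image at a high percentile of its own intensities — normalizes away the
  between-exam amplitude differences that the score is supposed to measure;
  on phantom cohorts it flattens the level trend for MIP scores and inverts
  it for AIP scores (the non-enhancing floor then scales like 1/amplitude).
  Percentile windowing remains available (`window_max = NULL`,
  `window_percentile`). When it is used, the window is computed from the
  pre-removal projection and shared with the removed variant so both are on
  one intensity scale.
* **"Rescaled" mode.** The default rescaled score divides the quantized
  image by 255, the literal 0–255 → 0–1 mapping. A per-image min–max
  normalization (`mode = "minmax"` in `rescale_image`) is also implemented;
  we do not use it by default because dividing by the image's own maximum
  again cancels amplitude (the score degenerates to a coverage-to-max ratio
  whose noise-floor term is non-monotone across the two lowest levels for
  any realistic floor), and because removing a bright lesion *raises* a
  min–max-normalized mean, contradicting the monotone-reduction property the
  removal step is designed to have.

The shared fixed window also yields two exact invariants that the tests
assert bit-for-bit: the unaffected breast's score is identical before and
after removal, and removal never changes any pixel outside the lesion mask.

## The phantom generator

`generate_study` builds bilateral breast anatomy on a default
24 x 128 x 128 grid at 2 x 1 x 1 mm spacing: two half-ellipsoid breasts
anterior to a flat chest-wall band, wide enough to meet in a thin medial
bridge (so the "largest object" really is one region containing both
breasts, as the post-processing requires). FGT is a blurred Gaussian random
field thresholded to a programmed volume fraction (default 0.20); an
independent nested field selects the *enhancing* subset of FGT.

Enhancement follows `intensity(t) = base + amplitude * uptake(t)` with
uptake 0.6 at the first and 1.0 at the second post-contrast time point. The
four BPE levels map to a strictly increasing pair: enhancement amplitude at
(0.10, 0.25, 0.45, 0.70) of the 200-unit lesion-free dynamic range, and
enhancing-FGT fraction (0.30, 0.50, 0.70, 0.90). Fat and chest wall enhance
faintly (amplitudes 6 and 2) — enough that the breast outline is visible on
a subtraction MIP, as it is in practice. The optional lesion is a sphere of
programmed diameter whose amplitude is the FGT amplitude times a contrast
multiplier (default 3), and additive Gaussian noise (default SD 2, clipped
at 0) is applied per volume. A `(spec, seed)` pair is a pure function of its
arguments, bit-identical on re-run.

What the phantom does *not* emulate: pharmacokinetics (no Tofts-style
curves), Rician noise statistics, coil inhomogeneity, motion, vasculature,
and any realistic FGT morphology distribution — the blob field is a
stand-in. Tests passing on phantoms therefore demonstrate that the
*algorithmic contracts* hold (segmentation recovers known geometry, removal
changes exactly what it should, scores order programmed levels), not that
the method achieves any particular accuracy on clinical images.

## Evaluation choices

* **Kendall tau-b** uses the tie-corrected denominator and the standard
  tie-corrected variance of S for its normal-approximation z-test; with
  heavy rating ties this matches `cor.test`'s behavior, which the tests
  cross-check.
* **ROC analysis** defaults to the empirical Mann–Whitney AUC (ties 0.5)
  with the DeLong variance estimator — verifiable against exhaustive pair
  counting, which the tests do. A conventional binormal maximum-likelihood
  fit on rank-binned data is available (`method = "binormal"`); the
  degenerate-free "proper" binormal model is intentionally not
  reimplemented, and with a single-valued score vector the empirical AUC is
  reported as 0.5 with an infinite standard error and a warning.
* **Bonferroni correction** multiplies the raw p by a caller-supplied family
  size and caps at 1; the family is the caller's choice.
* Dichotomization: minimal-vs-marked drops the two middle levels;
  low-vs-high keeps all exams (minimal+mild vs moderate+marked).

## Problem sizes used by the tests and the acceptance script

The shipped verification runs use a 60-phantom cohort (15 per level, lesion
diameters 5–30 mm), a segmenter trained on 40 phantom MIPs for 25 epochs
with 10 held-out phantoms, a removal sweep at diameters {5, 15, 30} mm for
the minimal and marked levels, and a 1000-repetition null simulation at
n = 100 for the z-test's size. These sizes were chosen as the smallest
cohorts at which the ordinal trends and ROC summaries are stable across
seeds.

## Known limitations

* Scores are 2D (projection-based); the lesion is segmented in 3D but BPE
  is not.
* No inter-volume registration: misaligned time points are the caller's
  responsibility.
* Vasculature is not removed and can inflate MIP-based scores, exactly as it
  would clinically.
* On-disk I/O is NIfTI only (plus CSV manifests and JSON sidecars).
* The fallback segmenter is a convenience, not a validated method.
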