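# bpescore

Automated scoring of **background parenchymal enhancement (BPE)** on breast
dynamic contrast-enhanced MRI, with **electronic lesion removal**.

BPE — the contrast uptake of normal fibroglandular tissue — is clinically
rated on the ordinal BI-RADS scale (*minimal / mild / moderate / marked*) by
visual inspection, a process with substantial reader variability that a
bright tumor can inflate. `bpescore` is for imaging researchers who want an
objective, reproducible scalar in place of that rating. The pipeline:

1. builds post-minus-pre **subtraction volumes**;
2. segments the diagnosed lesion in 3D with **fuzzy c-means** clustering
   inside a supplied ROI box and reports its size as
   `sqrt(area at the center lesion slice)`;
3. **electronically removes** the lesion: on every slice through the lesion,
   lesion pixels are replaced with the mean intensity of the bordering
   pixels;
4. collapses the volume to **maximum- or average-intensity projections**
   (MIP / AIP);
5. masks the breasts with a small trainable **U-Net** (probability threshold
   0.25, largest 8-connected object, hole fill, vertical split at the
   bounding-box center into affected/unaffected breasts);
6. computes the **computer BPE score** — the mean 8-bit pixel intensity
   within a breast mask, on original (0–255) or rescaled (0–1) intensities —
   over the full variant grid
   `{both, affected, unaffected} × {MIP, AIP} × {1st, 2nd post-contrast} ×
   {original, rescaled} × {± lesion removal}`;
7. evaluates scores against ordinal ratings with **Kendall tau-b** (tie-
   corrected z-test), **empirical ROC analysis** (Mann–Whitney AUC, DeLong
   SE, z-test vs chance, Bonferroni correction) for the minimal-vs-marked and
   low-vs-high tasks, and the **after/before score ratio vs lesion size**.

A synthetic DCE-MRI **breast-phantom generator** with full ground truth
(breast/FGT/lesion masks, programmed BPE level) makes every stage trainable
and testable without clinical data.

## Worked example

```r
library(bpescore)

spec <- phantom_spec(bpe_level = "moderate", lesion_diameter_mm = 12,
                     lesion_side = "left", seed = 42)
phantom <- generate_study(spec)
phantom$study
#> <dce_study> phantom-moderate-42
#>   grid: 24 x 128 x 128  spacing: 2/1/1 mm
#>   post-contrast time points: 2  affected side: left  rating: moderate

sv  <- subtract(phantom$study, time_point = 2)
roi <- lesion_roi(phantom$truth$lesion_bbox, dim(phantom$study$pre))
lesion <- segment_lesion(sv, roi)
cat("lesion size:", round(lesion$size_mm, 1), "mm\n")
#> lesion size: 10.6 mm

result <- run_exam(phantom$study, pipeline_config(), roi = roi)
subset(result$records, region == "affected" & projection_type == "MIP" &
         time_point == 2 & rescale_mode == "rescaled")[, c("lesion_removed", "score")]
#>  lesion_removed     score
#>           FALSE 0.2416036
#>            TRUE 0.2250075
```

The affected-breast score drops from 0.242 to 0.225 once the lesion's
enhancement is removed (after/before ratio 0.931): without removal the
12 mm lesion would inflate the BPE estimate of this moderate-level exam.
`run_cohort()` repeats this over a cohort and returns the tau-b / AUC
summary tables; `inst/cli/bpe.R` exposes `phantom`, `score` and `demo`
subcommands for shell use.

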