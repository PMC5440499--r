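# t2starseg

Semi-automatic left-ventricular myocardial segmentation and pixel-wise T2\*
quantification for bright-blood multi-gradient-echo (MGE) short-axis cardiac
MRI.

Myocardial iron overload shortens the effective transverse relaxation time
T2\*; a segment median ≤ 20 ms at 1.5 T flags iron loading. T2\* is measured
by fitting the echo-train signal of each myocardial pixel with

    y = K · exp(−TE / T2*) + C

and pooling pixels over the myocardial contours — which makes the
quantification only as reproducible as the contours. On bright-blood MGE the
hyperintense blood pool degrades endocardial contrast, and manual contouring
is the dominant source of observer variability. `t2starseg` replaces it with
a semi-automatic chain that needs only minimal seeds per slice (a rough
mid-wall contour, an air-background point, and either the anterior RV
insertion point or traced RV-blood-pool/lung contours):

1. **Composite generation** — per-echo, per-region contrast-to-noise ratios
   `CNR = NF·|SI_s − SI_m|/σ_b` select the echoes (weighted 1, 2/3:1/3 or
   1/3 each) fused into a contrast-optimized composite image.
2. **Blood-pool delineation** — k-means clustering on a shortest-TE minus
   optimal-TE subtraction image, refined by two vector-field-convolution
   (VFC) active contours; papillary muscles and trabeculae are re-joined
   into the pool.
3. **Border detection** — a radial grid of one-pixel layers × 72 (basal,
   mid) or 40 (apical) angular segments around the pool; layer acceptance by
   a 20% coefficient-of-variation stop, two-cluster k-means refinement of
   the low-contrast walls, 70%/40% occupancy correction, a ±2-layer
   neighbour cap, and a final ±2-layer border optimization that minimizes
   quartile-fence outliers and excludes them from the mask.
4. **T2\* mapping and reporting** — bounded Levenberg–Marquardt fits per
   pixel, median T2\* per AHA 16-segment-model segment with iron flags,
   global and mid-septal summaries, CSV/NIfTI/JSON outputs.
5. **Reproducibility statistics** — Dice coefficient, Bland–Altman limits of
   agreement, test–retest CoV and ICC(2,1) between repeated runs.

A synthetic short-axis phantom (annular myocardium with a focal low-T2\*
sector, bright LV/RV pools, lung, chest fat, Rician noise, known ground
truth and synthesized seeds) makes every stage testable end to end; see the
methods vignette (`vignettes/t2star-segmentation-methods.Rmd`) for the model
and every numerical choice.

## Worked example

Segment the default three-slice phantom set and compare two runs with
independently jittered seeds:

```r
library(t2starseg)

set <- phantom_slice_set(noise_sigma = 45, rng_seed = 20260920)
slices <- lapply(set, function(x) list(series = x$series,
                                       seeds = x$truth$seeds_method2))
run <- run_pipeline(slices, pipeline_config(method = 2L, seed = 1))
print(run)
#> <t2star_run> 3 slice(s) segmented
#>   global T2*: 26.18 ms; mid-septal T2*: 25.03 ms

run$slices$mid$composite$selection$weights   # echoes fused for the mid slice
#>      2.69     18.86
#> 0.6666667 0.3333333
round(run$slices$mid$composite$cnr_gain_pct, 1)  # composite vs best single TE
#> LVBP RVBP lung
#> 16.2 24.1 13.6

subset(run$summary$segments, slice_level == "mid")
#>    aha_segment_id      segment_name median_t2star_ms n_pixels iron_flag
#> 7               7      mid_anterior            27.47       85     FALSE
#> 8               8  mid_anteroseptal            22.88      105     FALSE
#> 9               9  mid_inferoseptal            27.19       73     FALSE
#> 10             10      mid_inferior            32.00       97     FALSE
#> 11             11 mid_inferolateral            15.71       75      TRUE
#> 12             12 mid_anterolateral            25.20      100     FALSE
```

The phantom's mid slice carries a focal inferolateral sector generated at
T2\* = 15 ms: segment 11 is recovered at 15.71 ms and is the only segment
flagged for iron. A repeat run with an independent 0.5-px jitter of the
manual seeds quantifies reproducibility:

```r
slices2 <- lapply(set, function(x) list(series = x$series,
  seeds = synthesize_seeds(x$truth, 2L, jitter = 0.5, seed = 77)))
run2 <- run_pipeline(slices2, pipeline_config(method = 2L, seed = 1))
compare_runs(list(run, run2))
#> <repro_report> n = 16 segments
#>   DSC: 0.977 +/- 0.023 (median +/- MAD)
#>   T2* mean difference +0.257 ms, LoA 3.586 ms, CoV 4.86%, ICC 0.973
```

Series and seeds can equally be given as file paths (NIfTI + JSON sidecar,
seeds JSON); `inst/scripts/run_pipeline.R` wraps the same call for shell
use (`Rscript run_pipeline.R --demo --out-dir out/`).

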