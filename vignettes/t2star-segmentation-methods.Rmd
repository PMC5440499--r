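---
title: "Methods: semi-automatic myocardial segmentation and T2* quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic myocardial segmentation and T2* quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2starseg)
```

## The problem

Myocardial iron overload (thalassemia, hemochromatosis, transfusion-dependent
anemias) shortens the effective transverse relaxation time T2* of the heart
muscle; a segment median at or below 20 ms is the accepted flag for iron
loading at 1.5 T. T2* is measured from a breath-hold multi-gradient-echo
(MGE) series: the same short-axis slice imaged at, typically, eight echo
times, with the signal decaying as `K * exp(-TE/T2*)`. The quantification is
only as reproducible as the myocardial contours it is pooled over, and on
bright-blood MGE images the blood pool is hyperintense, which makes manual
endocardial delineation the dominant source of observer variability.

`t2starseg` implements a semi-automatic chain that replaces the manual
contours: the observer supplies only minimal seeds (a rough mid-wall contour,
an air-background point, and either the anterior RV insertion point or traced
RV blood pool and lung contours), and the package derives the contours and
the segmental T2* report automatically. A synthetic short-axis phantom with
known ground truth makes the whole chain testable without patient data.

## Composite image generation

The contrast between myocardium and each of its surroundings — LV blood pool
(LVBP), RV blood pool (RVBP) and lung — peaks at different echo times,
because the tissues decay at different rates. Per echo and region the
contrast-to-noise ratio is

    CNR = NF * |SI_s - SI_m| / sigma_b

with `SI_s` the mean intensity of the surrounding-region ROI, `SI_m` the mean
along the one-pixel mid-wall band, `sigma_b` the standard deviation of an
air-background ROI, and `NF` a noise factor. `NF` cancels out of the argmax
over echoes, so its default of 1 has no effect on segmentation; it is kept
configurable for comparability of reported CNR values. For each region the
echo of maximal CNR is selected (ties go to the shorter, higher-SNR echo) and
the selected echoes are fused into one composite image, weighted 1, 2/3:1/3,
or 1/3 each depending on whether one, two or three distinct echoes were
chosen. All later segmentation runs on this composite.

Two ROI-placement methods are provided. Method 1 divides the wall into 4
(apical) or 6 angular sectors anchored at the manually marked anterior RV
insertion point and extrapolates two sector junction rays outward to place
the RVBP and lung ROIs (on apical slices, where RVBP and lung are small,
their approximate locations are marked manually). Method 2 takes traced RVBP
and lung contours instead; the insertion points then come automatically from
the two endpoints of the RVBP polyline, and the lung ROI is chosen among
candidate positions inside the lung contour as the one with minimum intensity
variance on the shortest-TE image, which keeps it out of lung vessels.

Defaults and their reasons:

* circular ROIs of radius 3 px — small enough to stay inside each structure
  on all slice levels;
* air box 9×9 px, with `sigma_b` estimated once from the air pixels pooled
  across all echoes — magnitude-MRI background noise does not depend on TE,
  and a per-echo SD from a small box carries enough sampling error to
  perturb the TE argmax. The composite's noise level is then obtained by
  propagation, `sqrt(sum(w^2))` times the pooled SD, since the composite is
  a known linear combination of independently acquired echoes; the reported
  CNR gains therefore reflect contrast and weighting, not the luck of one
  small ROI's SD estimate;
* method-1 extrapolation distance 1.5× the center-to-mid-wall distance along
  the junction ray — lands beyond the epicardium but inside the neighbouring
  structure for normal-sized ventricles;
* method-1 sector rotation follows the standard short-axis display
  orientation (RV on the viewer's left); method 2 infers the rotation sense
  from its two insertion points and does not need the convention;
* on strictly noiseless input (synthetic data) the air SD is floored at
  `1e-6` of the series maximum, one constant for all echoes, so that the TE
  selection — which is scale-invariant — remains defined.

## Part I: LV blood-pool delineation

Working against the bright-blood contrast directly is fragile, so the pool
is first located on a *subtraction image*: shortest-TE echo minus the echo
giving optimal LVBP contrast, clipped at zero. Blood, with its slow decay,
nearly cancels and becomes dark and homogeneous; myocardium keeps strong
signal. Pixels enclosed by the mid-wall seed contour are k-means clustered
(k = 3 by default: blood, transition, myocardium/artefact; k is reduced when
synthetic noiseless data carries fewer distinct values). Every cluster whose
center lies closer to the lowest center than to the highest is retained as
blood — with three clusters on what is really a two-population mixture,
retaining only the single lowest cluster would keep just the lower tail of
the blood distribution. The connected component containing the region
centroid forms the blood-pool core; papillary muscles, which carry
myocardial signal, are excluded at this stage.

The pool shape is then refined with vector-field-convolution (VFC) active
contours. The VFC field is the convolution of an edge map (gradient
magnitude of the Gaussian-smoothed image, sigma = 1 px, normalized to [0,1])
with the radially attracting kernel

    K(x, y) = (r + eps)^(-gamma) * (-x/r, -y/r),   r <= kernel_radius,

computed by zero-padded FFT and equal to direct summation to floating-point
accuracy. The closed snake evolves semi-implicitly: tension and rigidity are
handled through the periodic pentadiagonal stiffness matrix, the field is
interpolated bilinearly at sub-pixel vertices, and the vertex set is
resampled to uniform arc length every iteration. Defaults (kernel radius 32
px, gamma 1.7, eps 1e-8, alpha 0.3, beta 0.1, step 0.5, at most 300
iterations, stop at mean displacement < 0.05 px, 100 vertices) sit in the
middle of the ranges used in the VFC literature and are all configurable.

A first snake, initialized on the blood-cluster boundary, evolves against
the subtraction-image edge map; a second snake, initialized on the first
result dilated by 2 px, evolves against the composite-image edge map and
re-joins papillary muscles and trabeculae into the pool. Two implementation
decisions matter here:

* each snake is a *refinement*: its interior is clipped to the 2-px band
  around its own initialization, so a strong edge elsewhere in the image
  cannot drag the contour through the myocardial wall;
* the final region is the union of the filled second contour with the
  clustered blood component. A blood pixel left outside the pool would land
  in the first radial layer of Part II and poison the coefficient-of-
  variation statistics there irrecoverably, whereas a pool that reaches a
  pixel too far into the wall is recoverable by the border optimization.

## Part II: myocardial border detection

A *radial layer grid* is built around the pool: one-pixel-thick expansion
layers (successive unit-disc dilations, i.e. Euclidean distance rings)
crossed with radial segments about the pool centroid — 72 segments on basal
and mid-ventricular slices, 40 apically, so that innermost-layer cells hold
at most two pixel stacks. Layers extend to 14 mm (basal/mid) or 8 mm
(apical), past any plausible wall thickness. Cells left empty by the angular
discretization carry no evidence and are skipped, not treated as stops.

The epicardial border is then found in four steps.

1. **CoV expansion.** Starting from the adjacent segment pair whose combined
   innermost-layer pixels have the smallest coefficient of variation
   (SD/mean), each segment accepts layers outward until the CoV of its
   accumulated pixels, including the candidate layer, exceeds 20%. The
   cumulative form is used because a single candidate cell holds only 1–2
   pixels — far too few for a stable CoV on its own (a per-layer mode is
   configurable). Crossing into lung (signal drop) or fat (signal jump)
   trips the threshold immediately.
2. **k-means refinement** on the anterior/septal/posterior walls, where the
   epicardial contrast is weakest: the accepted pixels are split into two
   intensity clusters and the inner cluster — the one holding the majority
   of the two innermost layers' pixels — is retained; a layer stays accepted
   while at least half of its pixels belong to it. When the two cluster
   means differ by less than the CoV threshold relative to their pooled
   mean, the split reflects noise rather than two tissues and the counts
   pass through unchanged. The lung-adjacent lateral sectors are never
   modified by this step.
3. **Occupancy correction.** Within each anatomical wall position, outermost
   layers whose accepted pixel total falls below 70% (anterior, septal,
   posterior) or 40% (lateral) of the position's maximum per-layer total are
   stripped, iterating inward. The totals are taken per wall position, not
   per 1–2-pixel cell, where a percentage would be meaningless.
4. **Neighbour capping.** Accepted counts may differ by at most 2 between
   circular neighbours; the larger value is always reduced. The fixed point
   of that relaxation is computed in closed form as the circular lower
   envelope `a'[s] = min_t (a[t] + 2*dist(s, t))`, which makes the result
   independent of sweep order.

Finally the **border optimization** tests all 25 global combinations of
endocardial and epicardial shifts within ±2 layers. Homogeneity is judged
relative to the whole myocardium: quartile fences
`[Q1 - 0.9825*IQR, Q3 + 0.9825*IQR]` are computed once from the intensity
distribution of the initial annulus, and for each candidate the pixels of
its innermost and outermost one-pixel layers outside the fences count as
outliers. Three numerical choices deserve explanation:

* *Fences as Tukey-style IQR multiples.* Bounds placed directly at a small
  multiple of the quartiles themselves (e.g. `0.9825*Q1`) would span ±1.75%
  of the median and flag the majority of pixels at any realistic noise
  level, making the minimum-outlier criterion vacuous; fences a fixed
  multiple of the IQR beyond the quartiles scale with the data's own spread.
* *Fences from the initial annulus, not per candidate.* Quartiles computed
  on a candidate's own pixels explode as soon as a candidate swallows more
  than a quartile's worth of blood or fat, rewarding exactly the worst
  candidates.
* *Excess rate and tie policy.* Even a perfect border has fence outliers —
  the distribution's own tails — in proportion to its length, which would
  systematically favour compressed candidates. Candidates are therefore
  scored by their border outlier rate in excess of the candidate's
  whole-myocardium rate, differences within 2 percentage points (the
  sampling noise of the rate at these border sizes) count as ties, and
  among tied candidates the largest annulus wins: expansion stops exactly
  where the border starts collecting foreign tissue. The winning
  combination's outlier pixels are excluded from the final myocardial mask.

## T2* quantification

Each myocardial pixel's intensities across the echo train are fitted with
the monoexponential-plus-offset model

    y = K * exp(-TE / T2*) + C,

by bounded Levenberg–Marquardt least squares (T2* in (0.1, 500] ms,
convergence at relative change 1e-8 or 500 iterations), initialized from a
log-linear fit of `y - min(y) + eps`. The offset absorbs the Rician noise
floor that otherwise biases T2* low at high iron burden. Estimates that
settle on a T2* bound are reported at the bound and kept: at realistic SNR
the estimator for long-T2* myocardium is heavy-tailed, and censoring only
the runaway tail would bias segment medians low. Constant (zero-amplitude)
pixels are flagged as failed and excluded from medians.

Pixels are grouped by the AHA 16-segment model — six 60° segments on basal
and mid-ventricular slices, four 90° segments apically — anchored at the
anterior RV insertion ray, with the rotation sense toward the septum taken
from the inferior insertion point. Each segment is summarized by its
*median* T2* (robust to single-pixel artefacts), flagged as iron-loaded at
≤ 20 ms. Global T2* is the unweighted mean of the 16 segment medians;
mid-septal T2* is the mean of the mid-anteroseptal and mid-inferoseptal
medians (AHA 8 and 9).

## Reproducibility statistics

Contour agreement uses the Dice similarity coefficient
`2|A∩B| / (|A|+|B|)`; two empty masks are defined to agree perfectly (with a
warning). T2* agreement between repeated runs uses the Bland–Altman mean
difference with limits of agreement `1.96*SD` of the paired differences, the
test–retest coefficient of variation in the within-pair RMS convention
`100 * sqrt(mean(d^2)/2) / grand mean` (the standard convention; reported
CoVs depend on it, so it is stated here prominently), and the two-way
random-effects, absolute-agreement, *single-measure* intraclass correlation
ICC(2,1) — the conservative choice when the model is stated but the
single/average distinction is not.

## The phantom

The synthetic phantom renders the forward model `K_r exp(-TE/T2*_r) + C` per
tissue on a 128×128 grid at 1.56 mm pixels with eight echoes (2.69–18.86 ms
in 2.31 ms steps), then applies Rician noise
`sqrt((img + g1)^2 + g2^2)`. Default tissue parameters, chosen from 1.5 T
physiology:

| tissue          | K    | T2* (ms) | note                                   |
|-----------------|------|----------|----------------------------------------|
| myocardium      | 1000 | 30       | normal; focal sector 15 (see below)    |
| LV blood        | 1800 | 150      | arterial, oxygenated                   |
| RV blood        | 1800 | 40       | venous, desaturated                    |
| lung            | 80   | 2        | low proton density, fast decay         |
| chest fat/body  | 2200 | 50       | brightest tissue on gradient echo      |
| air             | 0    | —        | strictly zero; offset C = 20 elsewhere |

The distinct LV/RV blood T2* is deliberate: venous desaturation shortens RV
blood T2*, which moves the RVBP contrast optimum to the shortest echo while
the LVBP optimum stays at the longest — the region-dependent echo selection
the composite stage exists for. Geometry (endocardial radius / wall, mm):
basal 26.5/9.4, mid 25.0/9.4, apical 18.7/7.7 — typical adult end-diastolic
dimensions with a basal-to-apical taper. The default mid-ventricular slice
carries a 40° inferolateral sector at T2* = 15 ms emulating focal iron, two
papillary-muscle discs with myocardial signal inside the pool, and a bright
vessel disc inside the lung. The default noise scale sigma = 45 puts the
myocardial SNR near 20 at the shortest echo. Seeds for both methods are
synthesized from the ground-truth geometry with 0.5 px Gaussian jitter
emulating observer variability.

What the phantom does *not* emulate — and what passing tests therefore do
not demonstrate about patient data: cardiac and respiratory motion,
susceptibility artefacts near the posterior wall and veins, flow artefacts
in the pool, partial-volume mixing beyond pixelation, coil-profile intensity
bias, and anatomy that deviates from nested near-circular shapes. The
tissue interfaces are also sharper than anything a scanner produces, which
makes sub-pixel contour placement *harder* than on real, slightly blurred
data, but makes intensity clustering easier.

## Problem sizes and numerics in the test suite

The suite exercises: full-pipeline runs on all three slice levels at
sigma = 0 and sigma = 45 (Dice against ground truth ≥ 0.95 noiseless,
≥ 0.85 at SNR ≈ 20; seed-jitter pairs ≥ 0.9); a 1000-replicate Monte-Carlo
of the decay fit at sigma = 5 (median within 2%); VFC fields against a
direct-summation oracle on grids up to 32×32 at 1e-8; exhaustive-partition
oracles for the 1-D clustering; a brute-force relaxation oracle for the
neighbour cap; and hand-computed worked examples for the agreement
statistics. All stochastic steps derive their streams from one global seed
via a per-stage counter scheme, so any stage can be re-run in isolation
reproducibly.

## Known limitations

* Input formats are NIfTI-1 volumes with JSON sidecars (and in-memory
  objects); DICOM directories are not read.
* No susceptibility-artefact masking and no truncation/R2*-correction
  fitting variants; the offset model is the only fitting mode.
* Pixel-wise T2* at SNR ≈ 20 is ill-conditioned for normal (long) myocardial
  T2* because the echo train samples only half a decay constant; segment
  medians are the reliable quantity, individual pixel values are not.
* The 20% CoV stop, the 70%/40% occupancy cut-offs and the 0.9825 fence
  factor are empirical constants inherited from the method; they are exposed
  in `border_config()` but have not been re-optimized here.
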