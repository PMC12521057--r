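---
title: "Global noise estimation for CT image quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global noise estimation for CT image quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ctgn)
```

## The problem

The CMS CT quality measure compares every exam against category-specific
thresholds for radiation dose and image noise. The noise side rests on a
single scalar per exam — the *global noise* (GN) level, in Hounsfield units
(HU) — estimated automatically from the patient images, without manual ROI
placement. Two published estimation families are in circulation, and they do
not agree numerically. `ctgn` implements both on a common chassis so that
their behaviour can be compared, audited, and exercised on synthetic phantoms
with known ground truth.

Five metrics are computed, named by their origin, the compartment they
measure in, and the histogram summary they use:

* `Duke_tissue_mode` — a sliding-window local standard-deviation noise map of
  the *unsegmented* slice, restricted to soft tissue, summarised by the
  histogram mode.
* `Wisconsin_tissue_mean`, `Wisconsin_tissue_mode`, `Wisconsin_air_mean`,
  `Wisconsin_air_mode` — adjacent-slice subtraction to cancel anatomy, a
  uniform 7 × 7 mm ROI grid on the difference image, per-ROI standard
  deviations inside the tissue or air mask, summarised by the histogram mean
  or mode.

Every metric is computed per slice and averaged across the scan to give the
exam-level value; for exams with several reconstructed series, the exam is
assigned the best (lowest-noise) value across scans.

## The two estimators in detail

### Duke soft-tissue mode

For a slice $I$ with pixel spacing $\Delta$, a square window of side
$w$ = 7 mm (converted to the nearest odd pixel count, minimum 3, ties
rounded up) slides over the *raw* slice. The sample standard deviation
(denominator $n-1$) of each window is assigned to its central pixel, giving
a noise map $N(x,y)$. No padding is used: border pixels whose window exits
the slice carry no value, which avoids fabricating data at the cost of a
negligible border strip on 512² clinical slices. The soft-tissue mask —
pixels with raw HU in $[0, 100]$ — is applied to $N$, the surviving values
are histogrammed, and the slice GN is the modal bin centre. Windows near the
body contour mix tissue and air and inflate the SD; the mode is robust to
that tail, which is precisely why it is used instead of the mean here.

### Wisconsin difference-image metrics

Anatomy is suppressed by subtracting each slice from its adjacent
neighbour (the last slice pairs with its previous neighbour so every slice
has one difference image). For uncorrelated equal noise the difference has
standard deviation $\sigma\sqrt{2}$. The *original* (minuend) slice is
median-filtered (3 × 3 by default) and thresholded — tissue $[0, 100]$ HU,
air $[-1024, -950]$ HU, both ends inclusive — and the difference image is
tiled with a uniform grid of 7 × 7 mm square ROIs anchored at the first
pixel, partial edge tiles discarded. Only ROIs wholly inside the compartment
mask contribute. Each contributes its sample SD; with the $\sqrt{2}$
correction enabled (the default) the SDs are divided by $\sqrt{2}$ so the
reported value estimates single-image noise. The slice GN is the arithmetic
mean of the ROI SDs (`*_mean`) or their modal histogram bin centre
(`*_mode`).

The $\sqrt{2}$ correction is a flag rather than a constant because the two
conventions both exist in practice; results record which was used, and with
the correction off the estimator targets $\sigma\sqrt{2}$ instead of
$\sigma$. Whether air ROIs should include the background air around the
patient is equally convention-dependent; the default includes all in-FOV
air, and `exclude_background_air` restricts to internal gas.

### Histogram modes

All mode summaries share one histogram convention: bins of width 0.5 HU
*centred* on multiples of the width, ties resolved toward the lowest bin.
Centre-aligned bins make degenerate inputs behave sensibly — a slice whose
masked SDs are all exactly 5.0 HU reports 5.0, and a noiseless phantom
reports exactly 0 — and the tie rule makes results deterministic. 0.5 HU
resolves the clinical GN range (roughly 5–100 HU) while keeping bins
populated; it is configurable (`histogram_bin_hu`).

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `duke_window_mm` | 7 | mm | local-SD window side; 6–20 mm give consistent results |
| `wisconsin_roi_mm` | 7 | mm | ROI side on the difference image |
| `histogram_bin_hu` | 0.5 | HU | bin width for all modes |
| `tissue_hu_range` | [0, 100] | HU | soft-tissue threshold window (inclusive) |
| `air_hu_range` | [-1024, -950] | HU | air threshold window (inclusive) |
| `median_kernel_px` | 3 | px | median filter before Wisconsin thresholding |
| `sqrt2_correction` | TRUE | — | undo variance doubling of the subtraction |
| `min_mask_pixels` | 100 | px | Duke sparse-slice cutoff ("no value" below) |
| `min_valid_rois` | 5 | ROIs | Wisconsin sparse-slice cutoff |

Threshold bounds are applied inclusively at both ends: the published
descriptions say "between 0 and 100 HU" without specifying open or closed
intervals, and inclusive is the least surprising reading. Stored values that
calibrate below −1024 HU (field-of-view padding, often −2048) are clamped to
−1024 *for segmentation only*, so padding classifies as air rather than as
impossibly dense material; SD computations always see the unclamped HU so
that genuine noise excursions below −1024 around air are not censored.

## The phantom generator

`make_phantom()` builds the synthetic study conditions: an elliptical
soft-tissue body (50 HU, default 300 × 200 mm) on an air background
(−1000 HU), on a 512 × 512 grid at 0.7 mm spacing and 3 mm slice thickness
— the CMS reference thickness — with optional disc or rectangle inserts
replicated identically on every slice as anatomy surrogates. Zero-mean
Gaussian noise of target SD `sigma_hu` is drawn independently per slice.
A `kernel_fwhm_mm` > 0 correlates the noise with an isotropic Gaussian
filter, emulating a smooth reconstruction kernel; white noise emulates a
sharp one. By default the filtered field is rescaled so the *marginal* SD
equals `sigma_hu` exactly; switching `rescale_noise` off instead fixes the
pre-filter amplitude, which is the physically meaningful comparison when
demonstrating that a smooth kernel lowers measured GN at equal input noise.
Final HU values are snapped to the 0.1 HU DICOM storage grid (slope 0.1,
intercept −1024), so a written series reloads bit-exactly.

What the phantom deliberately does *not* emulate: projection-domain physics
(beam hardening, photon starvation), realistic noise power spectra of named
kernels, inter-slice noise correlation, and anthropomorphic texture. Passing
recovery tests on these phantoms therefore demonstrates that the estimators
are correctly implemented and unbiased under their own assumptions — not
that any metric is accurate on patient data, which is exactly the
inter-metric disagreement the package exists to expose.

```{r phantom-example}
p <- make_phantom(phantom_spec(shape = c(4, 256, 256), sigma_hu = 10,
                               body_axes_mm = c(120, 90), seed = 1))
compute_exam_gn(p$volume)
```

## Statistics

Protocol-level comparisons use the Friedman test on within-exam ranks,
pairwise two-sided Wilcoxon signed-rank tests with Holm step-down
adjustment (zero differences discarded; exact null for up to 25 untied
differences, normal approximation with continuity correction beyond), and
Pearson correlation matrices with the conventional strength bins
(very strong $r \ge 0.8$, strong $0.6 \le r < 0.8$, moderate
$0.4 \le r < 0.6$, weak $0.2 \le r < 0.4$).

Patient-level comparisons use a linkage-preserving paired permutation test:
an exam is a matched set of per-slice values from two metrics, the observed
statistic is $|\overline{A - B}|$ over slices, and the null flips the sign
of each per-slice difference independently — the label swap is within a
slice, so slice-to-slice structure is untouched. The mean difference was
chosen as the statistic because the exam-level GN is itself a slice mean;
the published description names the test but not the statistic. With 20 or
fewer slices the $2^n$ sign patterns are enumerated exhaustively (via a
meet-in-the-middle split, so 20 slices cost two vectors of 1024 sums);
beyond that a seeded Monte-Carlo draw is used with the add-one estimator
$p = (1 + \#\{|\bar d_\text{null}| \ge |\bar d_\text{obs}|\})/(1 + B)$,
which cannot report zero and keeps the test valid.

```{r permutation}
paired_permutation_exam(c(1, 1), c(0, 0))$p_value       # 2 slices: 2/4
paired_permutation_exam(rep(1, 12), rep(0, 12))$p_value  # 2/4096
```

## Numerical and design choices

* **Sample SD everywhere** ($n-1$): the standard noise estimator; recorded
  so both Wisconsin conventions are reproducible.
* **Local SD maps** are computed by a per-window two-pass mean/deviation
  pass in C++, deliberately mirroring the brute-force definition instead of
  an integral-image shortcut; summed-area tables lose up to half the
  significand to cancellation on HU-scale values, and the two-pass form
  agrees with direct recomputation to better than $10^{-9}$ HU.
* **Median filter** is an exact order-statistic filter (replicate borders);
  approximate histogram-based median filters quantise the output, which
  breaks exact-threshold semantics at the mask boundaries.
* **Window/ROI size conversion**: nearest odd pixel count with upward ties
  for the Duke window (7 mm at 0.7 mm/px → 11 px), plain rounding with a
  floor of 2 px for ROI sides; degenerate geometries (ROI smaller than 2 px,
  window larger than the slice) are hard errors.
* **"No value" propagation**: slices whose mask keeps fewer than
  `min_mask_pixels` pixels (Duke) or fewer than `min_valid_rois` ROIs
  (Wisconsin) yield no value and are excluded — and counted — in the
  exam mean. An exam whose slices all fail reports no value rather than a
  fabricated fallback, mirroring the unresolved status of such exams in the
  measure itself.
* **Compliance boundary**: an exam *exceeds* its category threshold only
  when strictly above it; equality is within.
* **Best-scan ties** keep the first scan in series order, logged in the
  result.
* **Slice pairing**: adjacency is index-based; non-uniform slice spacing is
  tolerated with a warning since the subtraction is defined per neighbour,
  not per millimetre.

## DICOM handling

Volumes are read from and written to single-frame CT DICOM series (explicit
VR little endian). Slices are ordered by the axial image-position
coordinate, falling back to instance number with a warning when positions
are absent; loading is independent of file discovery order. HU calibration
is `stored * RescaleSlope + RescaleIntercept`, applied before any metric
sees the data. Directories mixing several series require an explicit series
selector. Compressed transfer syntaxes, sequences, multi-frame enhanced CT
and non-axial objects are rejected with explicit errors.

## Problem sizes used in the test suite

The bundled tests exercise full-scale 512 × 512 phantoms with 2–20 slices
for the recovery, window-robustness, kernel-direction and
structure-suppression experiments, and 32–256 px phantoms for unit-level
checks; the permutation calibration uses 200 simulated null exams of 30
slices at 2000 permutations each. These sizes were chosen as the smallest
that make the statistical assertions stable across seeds.

## Known limitations

* The reader supports the subset of DICOM the writer emits plus typical
  uncompressed single-frame CT; it is not a general DICOM toolkit.
* Air metrics are undefined on exams without in-FOV air (small-FOV cardiac,
  very large habitus); the package reports "no value" for them.
* The 3 mm slice-thickness standardisation mentioned in the measure is not
  implemented — its definition is unspecified — so volumes are analysed at
  their native thickness.
* Exam categories are user-assigned; no automatic protocol detection from
  DICOM headers is attempted.
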