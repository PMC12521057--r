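# ctgn — global noise estimation for CT image quality assessment

The CMS CT quality measure scores every exam against category-specific
thresholds for radiation dose and image noise. The noise side hinges on a
single scalar, the **global noise (GN) level** in Hounsfield units,
estimated automatically from the patient images — but the measure does not
define *how*, and the two published estimation families it references
disagree numerically. `ctgn` is for medical physicists and imaging
scientists who need to compute, compare, and audit these estimators: it
implements all five metrics on one chassis, aggregates them to exam level,
classifies exams against CMS thresholds, and ships a phantom simulator so
every number the package produces can be verified against known ground
truth without patient data.

## The five metrics

For each axial slice:

* **Duke_tissue_mode** — slide a 7 mm square window over the *unsegmented*
  slice and assign each window's sample standard deviation to its central
  pixel (a noise map); keep map values under the soft-tissue mask
  (0–100 HU on the raw slice); report the modal histogram bin centre.
* **Wisconsin_{tissue,air}_{mean,mode}** — subtract each slice from its
  adjacent neighbour to cancel anatomy; tile the difference image with a
  uniform 7 × 7 mm ROI grid; keep ROIs wholly inside the tissue
  (0–100 HU) or air (−1024 to −950 HU) mask thresholded on the
  median-filtered original slice; take each ROI's sample SD, divided by
  √2 to undo the variance doubling of the subtraction (configurable);
  report the mean or the modal bin centre of the ROI SDs.

Slice values are averaged across the scan for the exam-level value; exams
with several reconstructed series are assigned the best (lowest-noise)
scan, and exam values compare against CMS thresholds by strict exceedance.

## Worked example

Generate a known-noise phantom (12 HU white noise, elliptical soft-tissue
body on air) and recover the noise with all five metrics:

```r
library(ctgn)

p <- make_phantom(phantom_spec(shape = c(4, 256, 256), sigma_hu = 12,
                               body_axes_mm = c(120, 90), seed = 42))
compute_exam_gn(p$volume)
#> # A tibble: 5 × 6
#>   exam_id   scan_id  metric                exam_gn n_slices_used n_slices
#>   <chr>     <chr>    <chr>                   <dbl>         <int>    <int>
#> 1 phantom-1 series-1 Duke_tissue_mode         12               4        4
#> 2 phantom-1 series-1 Wisconsin_tissue_mean    12.1             4        4
#> 3 phantom-1 series-1 Wisconsin_tissue_mode    11.8             4        4
#> 4 phantom-1 series-1 Wisconsin_air_mean       12.0             4        4
#> 5 phantom-1 series-1 Wisconsin_air_mode       11.8             4        4
```

Every metric reads the injected 12 HU to within a histogram bin: the
phantom satisfies each estimator's assumptions, so disagreement on real
anatomy is attributable to the metrics, not the implementation. Exam
values classify against the bundled CMS thresholds (here, the routine-dose
abdomen/pelvis category, 29 HU):

```r
res <- compute_exam_gn(p$volume)
classify_compliance(res$exam_gn, "abdomen_pelvis_wo")
#> [1] "within" "within" "within" "within" "within"
```

Real exams enter through `load_ct_series()` (single-frame CT DICOM;
`write_ct_series()` writes phantoms through the same path), and whole
directory trees through `cmd_compute()`. Cohort tables feed
`gn_compare()`, which runs the Friedman omnibus, pairwise Wilcoxon tests
with Holm adjustment, Pearson correlations with strength labels, and
per-exam linkage-preserving permutation tests; results have `tidy()` /
`glance()` methods and `plot_gn_box()` / `plot_gn_heatmap()` graphics. A
command-line wrapper with `compute`, `compare` and `simulate` subcommands
lives at `inst/cli/ctgn.R`.

See `vignettes/ct-global-noise.Rmd` for the models, parameter defaults,
and numerical choices.

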