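Package: ctgn
Title: Global Noise Estimation for CT Image Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the five global-noise (GN) metrics used for CT image
    quality assessment under the CMS CT quality measure: the Duke soft-tissue
    histogram-mode metric (sliding-window local standard-deviation noise map)
    and the four Wisconsin metrics (adjacent-slice subtraction, uniform 7 mm
    ROI grid, tissue/air segmentation, histogram mean and mode). Reads and
    writes single-frame CT DICOM series, aggregates slice values to exam
    level, selects the best scan for multi-scan exams, and classifies exams
    against CMS noise thresholds. Includes a synthetic phantom generator with
    known noise ground truth, cohort-comparison statistics (Friedman, pairwise
    Wilcoxon with Holm adjustment, Pearson correlation with strength labels,
    linkage-preserving paired permutation tests), and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
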