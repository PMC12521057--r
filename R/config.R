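#' Analysis configuration for global-noise computation
#'
#' Bundles every tunable of the Duke and Wisconsin metrics so a whole run can
#' be reproduced from one object. All lengths are millimetres, all intensities
#' Hounsfield units (HU). The defaults follow the published methods: a 7 mm
#' Duke sliding window matched to the 7 x 7 mm Wisconsin ROI, soft tissue
#' thresholded at 0--100 HU, air at -1024 to -950 HU (both ends inclusive).
#'
#' @param duke_window_mm Side of the Duke local-SD sliding window (mm).
#' @param wisconsin_roi_mm Side of the square Wisconsin ROIs (mm).
#' @param histogram_bin_hu Histogram bin width (HU) used for every mode
#'   estimate. Bins are centred on multiples of the width so that, e.g., a
#'   degenerate set of identical SD values reports exactly that value.
#' @param tissue_hu_range Inclusive soft-tissue HU window, length 2.
#' @param air_hu_range Inclusive air HU window, length 2.
#' @param median_kernel_px Odd side of the median filter applied before
#'   Wisconsin thresholding (pixels).
#' @param sqrt2_correction Divide Wisconsin difference-image SDs by sqrt(2) to
#'   undo the variance doubling of the slice subtraction (default `TRUE`).
#' @param min_mask_pixels Minimum masked noise-map pixels for a Duke slice
#'   value; sparser slices return no value.
#' @param min_valid_rois Minimum valid ROIs for a Wisconsin slice value.
#' @param exclude_background_air Drop air connected to the slice border
#'   (keeps only internal gas/lung) before ROI selection. Off by default: the
#'   air compartment then includes the background air around the patient.
#' @param pool_rois Pool ROI SDs from all slices into one exam-level
#'   histogram instead of summarising per slice and averaging. Off by
#'   default (slice-by-slice computation averaged across the scan).
#'
#' @return A list with class `"gn_config"`.
#' @examples
#' cfg <- gn_config(sqrt2_correction = FALSE)
#' cfg$wisconsin_roi_mm
#' @export
gn_config <- function(duke_window_mm = 7,
                      wisconsin_roi_mm = 7,
                      histogram_bin_hu = 0.5,
                      tissue_hu_range = c(0, 100),
                      air_hu_range = c(-1024, -950),
                      median_kernel_px = 3,
                      sqrt2_correction = TRUE,
                      min_mask_pixels = 100,
                      min_valid_rois = 5,
                      exclude_background_air = FALSE,
                      pool_rois = FALSE) {
  stopifnot(duke_window_mm > 0, wisconsin_roi_mm > 0, histogram_bin_hu > 0,
            length(tissue_hu_range) == 2, length(air_hu_range) == 2,
            diff(tissue_hu_range) >= 0, diff(air_hu_range) >= 0,
            median_kernel_px >= 3, median_kernel_px %% 2 == 1,
            min_mask_pixels >= 1, min_valid_rois >= 1)
  structure(list(
    duke_window_mm = duke_window_mm,
    wisconsin_roi_mm = wisconsin_roi_mm,
    histogram_bin_hu = histogram_bin_hu,
    tissue_hu_range = as.numeric(tissue_hu_range),
    air_hu_range = as.numeric(air_hu_range),
    median_kernel_px = as.integer(median_kernel_px),
    sqrt2_correction = isTRUE(sqrt2_correction),
    min_mask_pixels = as.integer(min_mask_pixels),
    min_valid_rois = as.integer(min_valid_rois),
    exclude_background_air = isTRUE(exclude_background_air),
    pool_rois = isTRUE(pool_rois)
  ), class = "gn_config")
}

#' @export
print.gn_config <- function(x, ...) {
  cat("<gn_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-24s %s\n", k, paste(format(x[[k]]), collapse = " .. ")))
  }
  invisible(x)
}

#' Names of the five global-noise metrics
#'
#' Column/metric identifiers in the canonical order used throughout the
#' package: the Duke soft-tissue mode and the four Wisconsin
#' compartment-summary combinations.
#'
#' @return Character vector of length 5.
#' @export
gn_metric_names <- function() {
  c("Duke_tissue_mode", "Wisconsin_tissue_mean", "Wisconsin_tissue_mode",
    "Wisconsin_air_mean", "Wisconsin_air_mode")
}
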