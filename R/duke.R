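# Duke global noise: sliding-window local-SD noise map on the unsegmented
# slice, soft-tissue mask applied to the map, histogram mode as the slice
# noise estimate.

#' Convert a physical window size to an odd pixel count
#'
#' Nearest odd integer to `window_mm / pixel_spacing_mm`, ties broken
#' upward, floored at 3 pixels.
#'
#' @param window_mm Window side in mm, > 0.
#' @param pixel_spacing_mm In-plane pixel spacing in mm, > 0 (scalar; use
#'   the row spacing for square-pixel CT).
#' @return Odd integer >= 3.
#' @examples
#' window_px_from_mm(7, 0.7)  # 10 px is even; the tie resolves upward to 11
#' @export
window_px_from_mm <- function(window_mm, pixel_spacing_mm) {
  if (window_mm <= 0 || pixel_spacing_mm <= 0) {
    stop("`window_mm` and `pixel_spacing_mm` must be positive", call. = FALSE)
  }
  q <- window_mm / pixel_spacing_mm
  lower <- 2 * floor((q - 1) / 2) + 1          # largest odd <= q (or q-1)
  upper <- lower + 2
  k <- if ((q - lower) < (upper - q)) lower else upper
  as.integer(max(3, k))
}

#' Local standard-deviation noise map of a slice
#'
#' Slides an odd square window over the unsegmented slice and assigns the
#' sample standard deviation (n - 1 denominator) of each window to its
#' central pixel. No padding is used: pixels whose window exits the slice
#' are invalid and carry `NA`.
#'
#' @param slice_hu Numeric matrix of HU values.
#' @param window_px Odd window side in pixels, >= 3; the slice must be at
#'   least this large in both dimensions.
#' @return A list of class `"noise_map"`: `sd_map` (matrix, `NA` outside
#'   the valid region), `valid` (logical matrix), `window_px`.
#' @export
local_sd_map <- function(slice_hu, window_px) {
  stopifnot(is.matrix(slice_hu), is.numeric(slice_hu))
  if (window_px < 3 || window_px %% 2 != 1) {
    stop("`window_px` must be an odd integer >= 3, got ", window_px, call. = FALSE)
  }
  if (nrow(slice_hu) < window_px || ncol(slice_hu) < window_px) {
    stop(sprintf("slice (%d x %d) smaller than the %d px window",
                 nrow(slice_hu), ncol(slice_hu), window_px), call. = FALSE)
  }
  sd_map <- local_sd_cpp(slice_hu, as.integer(window_px))
  structure(list(sd_map = sd_map, valid = !is.na(sd_map),
                 window_px = as.integer(window_px)),
            class = "noise_map")
}

# Histogram mode with bins centred on multiples of the bin width, so a
# degenerate value set reports itself exactly; ties go to the lowest bin.
hist_mode <- function(values, bin_width_hu) {
  idx <- as.integer(round(values / bin_width_hu))
  counts <- table(idx)
  modal <- as.integer(names(counts)[which.max(counts)])  # which.max: first max
  # table() orders integer names numerically ascending, so the first
  # maximal count is the lowest bin
  modal * bin_width_hu
}

# "no value" marker: NA with a reason, so aggregation can count exclusions
gn_no_value <- function(reason) structure(NA_real_, reason = reason)

#' Duke slice global noise
#'
#' Computes the local-SD noise map of the (unsegmented) slice, keeps the
#' map values under the soft-tissue mask and inside the valid window
#' region, histograms them, and returns the modal bin centre.
#'
#' @param slice_hu Numeric matrix of HU values.
#' @param pixel_spacing_mm In-plane spacing (mm), scalar or length-2.
#' @param tissue_mask Logical matrix congruent with the slice; defaults to
#'   thresholding the raw slice at the config's tissue window.
#' @param window_mm Sliding-window side (mm).
#' @param bin_width_hu Histogram bin width (HU).
#' @param min_mask_pixels Minimum surviving pixels; sparser slices return
#'   `NA` with a `reason` attribute ("no value").
#' @param tissue_hu_range Threshold window used when `tissue_mask` is NULL.
#' @return Slice GN in HU, or `NA` (reason attribute) for sparse masks.
#'   The number of contributing pixels is attached as attribute `n`.
#' @export
duke_slice_gn <- function(slice_hu, pixel_spacing_mm,
                          tissue_mask = NULL, window_mm = 7,
                          bin_width_hu = 0.5, min_mask_pixels = 100,
                          tissue_hu_range = c(0, 100)) {
  if (is.null(tissue_mask)) {
    tissue_mask <- make_mask(slice_hu, "tissue", use_median_filter = FALSE,
                             hu_range = tissue_hu_range)
  }
  stopifnot(identical(dim(tissue_mask), dim(slice_hu)))
  wpx <- window_px_from_mm(window_mm, pixel_spacing_mm[1])
  nm <- local_sd_map(slice_hu, wpx)
  keep <- tissue_mask & nm$valid
  n <- sum(keep)
  if (n < min_mask_pixels) {
    return(structure(gn_no_value(sprintf("only %d masked pixels (< %d)", n,
                                         min_mask_pixels)), n = n))
  }
  structure(hist_mode(nm$sd_map[keep], bin_width_hu), n = n)
}
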