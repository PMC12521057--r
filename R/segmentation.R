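#' Median-filter a CT slice
#'
#' Exact 2-D median filter with an odd square kernel and replicate borders,
#' used to denoise a slice before HU thresholding on the Wisconsin path.
#'
#' @param slice_hu Numeric matrix of HU values.
#' @param kernel_px Odd kernel side in pixels, >= 3.
#' @return Filtered matrix of the same dimensions; the input is untouched.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 100
#' median_filter_slice(m)[3, 3]
#' @export
median_filter_slice <- function(slice_hu, kernel_px = 3) {
  stopifnot(is.matrix(slice_hu), is.numeric(slice_hu))
  if (length(kernel_px) != 1 || kernel_px < 3 || kernel_px %% 2 != 1) {
    stop("`kernel_px` must be an odd integer >= 3, got ", kernel_px, call. = FALSE)
  }
  median_filter_cpp(slice_hu, as.integer(kernel_px))
}

#' Threshold a slice into a tissue or air mask
#'
#' Soft tissue is thresholded at 0--100 HU, air at -1024 to -950 HU (both
#' ends inclusive; the ranges are configurable). The Wisconsin method
#' thresholds the median-filtered slice (`use_median_filter = TRUE`); the
#' Duke method thresholds the raw slice.
#'
#' @param slice_hu Numeric matrix of HU values.
#' @param compartment `"tissue"` or `"air"`.
#' @param use_median_filter Apply [median_filter_slice()] before
#'   thresholding.
#' @param kernel_px Median kernel side, used when filtering is on.
#' @param hu_range Inclusive HU window, length 2; defaults to the
#'   compartment's standard window.
#' @param exclude_background_air For `"air"` only: drop air 4-connected to
#'   the slice border, keeping internal gas/lung.
#' @return Logical matrix with attributes `compartment` and
#'   `source_filtered`.
#' @export
make_mask <- function(slice_hu, compartment = c("tissue", "air"),
                      use_median_filter = FALSE, kernel_px = 3,
                      hu_range = NULL, exclude_background_air = FALSE) {
  compartment <- match.arg(compartment)
  if (is.null(hu_range)) {
    hu_range <- if (compartment == "tissue") c(0, 100) else c(-1024, -950)
  }
  stopifnot(length(hu_range) == 2, hu_range[1] <= hu_range[2])
  # FOV padding (e.g. -2048) is clamped to -1024 for segmentation only, so it
  # classifies as air rather than masquerading as ultra-dense material; SD
  # computations elsewhere always see the unclamped HU values.
  src <- pmax(slice_hu, -1024)
  if (use_median_filter) src <- median_filter_slice(src, kernel_px)
  mask <- src >= hu_range[1] & src <= hu_range[2]
  if (compartment == "air" && exclude_background_air) {
    mask <- mask & !flood_from_border(mask)
  }
  structure(mask, compartment = compartment,
            source_filtered = use_median_filter, hu_range = hu_range)
}

# 4-connected region of TRUE pixels reachable from the matrix border
flood_from_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  frontier <- mask
  frontier[2:(nr - 1), 2:(nc - 1)] <- FALSE
  while (any(frontier)) {
    reached <- reached | frontier
    grown <- matrix(FALSE, nr, nc)
    grown[-1, ] <- grown[-1, ] | reached[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -nc]
    grown[, -nc] <- grown[, -nc] | reached[, -1]
    frontier <- grown & mask & !reached
  }
  reached
}
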