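# Wisconsin global noise: adjacent-slice subtraction to cancel anatomy,
# uniform square ROI grid on the difference image, per-ROI SD within the
# tissue or air mask of the original slice, histogram mean and mode.

#' Subtract a slice from its adjacent neighbor
#'
#' Returns `slice[i] - slice[i + 1]`; the last slice pairs with its
#' previous neighbor (`slice[n] - slice[n - 1]`) so every slice has one
#' difference image.
#'
#' @param volume A [ct_volume()] with >= 2 slices.
#' @param slice_index Index of the minuend slice.
#' @return Difference matrix with attribute `pair` = `c(i, j)` recording
#'   the minuend and subtrahend indices.
#' @export
subtract_adjacent <- function(volume, slice_index) {
  stopifnot(inherits(volume, "ct_volume"))
  n <- n_slices(volume)
  stopifnot(slice_index >= 1, slice_index <= n)
  j <- if (slice_index < n) slice_index + 1L else slice_index - 1L
  structure(get_slice(volume, slice_index) - get_slice(volume, j),
            pair = c(as.integer(slice_index), j))
}

#' Build a uniform square ROI grid over a slice
#'
#' ROI side is `round(roi_mm / spacing)` pixels (minimum 2); the grid is
#' anchored at the first pixel and trailing partial rows/columns are
#' discarded.
#'
#' @param slice_shape Integer (rows, cols) of the slice.
#' @param roi_mm ROI side in mm.
#' @param pixel_spacing_mm In-plane spacing (mm), scalar or length-2.
#' @return A list of class `"roi_grid"`: `roi_px`, and `origins`, a tibble
#'   of 1-based upper-left (row, col) corners.
#' @examples
#' g <- build_roi_grid(c(512, 512), 7, 0.7)
#' g$roi_px; nrow(g$origins)
#' @export
build_roi_grid <- function(slice_shape, roi_mm, pixel_spacing_mm) {
  stopifnot(roi_mm > 0, all(pixel_spacing_mm > 0), length(slice_shape) == 2)
  roi_px <- max(2L, as.integer(round(roi_mm / pixel_spacing_mm[1])))
  if (round(roi_mm / pixel_spacing_mm[1]) < 2) {
    stop(sprintf("ROI of %g mm spans < 2 px at %g mm/px", roi_mm,
                 pixel_spacing_mm[1]), call. = FALSE)
  }
  if (roi_px > min(slice_shape)) {
    stop(sprintf("ROI of %d px exceeds the %d x %d slice", roi_px,
                 slice_shape[1], slice_shape[2]), call. = FALSE)
  }
  nr <- slice_shape[1] %/% roi_px
  nc <- slice_shape[2] %/% roi_px
  origins <- tidyr::expand_grid(row = (seq_len(nr) - 1L) * roi_px + 1L,
                                col = (seq_len(nc) - 1L) * roi_px + 1L)
  structure(list(roi_px = roi_px, origins = origins), class = "roi_grid")
}

#' Wisconsin slice global noise for one compartment
#'
#' Computes the adjacent-slice difference image, tiles it with the ROI
#' grid, keeps ROIs wholly inside the compartment mask (thresholded on the
#' median-filtered original slice), takes the sample SD of each kept ROI
#' on the difference image, optionally divides by sqrt(2) to undo the
#' variance doubling of the subtraction, and summarises the ROI SDs by
#' their arithmetic mean and histogram mode.
#'
#' @param volume A [ct_volume()].
#' @param slice_index Minuend slice index.
#' @param compartment `"tissue"` or `"air"`.
#' @param roi_mm ROI side (mm).
#' @param bin_width_hu Histogram bin width for the mode (HU).
#' @param sqrt2_correction Divide ROI SDs by sqrt(2) (default `TRUE`).
#' @param min_valid_rois Minimum valid ROIs; sparser slices return `NA`.
#' @param median_kernel_px Median filter kernel for segmentation.
#' @param hu_range Optional override of the compartment threshold window.
#' @param exclude_background_air See [make_mask()].
#' @return A one-row tibble: `compartment`, `mean_gn`, `mode_gn`,
#'   `n_rois`, plus `roi_sds` as a list-column; or `NA`-valued row with a
#'   `reason` when fewer than `min_valid_rois` ROIs survive.
#' @export
wisconsin_slice_gn <- function(volume, slice_index,
                               compartment = c("tissue", "air"),
                               roi_mm = 7, bin_width_hu = 0.5,
                               sqrt2_correction = TRUE, min_valid_rois = 5,
                               median_kernel_px = 3, hu_range = NULL,
                               exclude_background_air = FALSE) {
  compartment <- match.arg(compartment)
  diff_img <- subtract_adjacent(volume, slice_index)
  mask <- make_mask(get_slice(volume, slice_index), compartment,
                    use_median_filter = TRUE, kernel_px = median_kernel_px,
                    hu_range = hu_range,
                    exclude_background_air = exclude_background_air)
  grid <- build_roi_grid(dim(diff_img), roi_mm, volume$pixel_spacing_mm)
  sds <- roi_sd_cpp(diff_img, mask, grid$origins$row, grid$origins$col,
                    grid$roi_px)
  sds <- sds[!is.na(sds)]
  if (sqrt2_correction) sds <- sds / sqrt(2)
  if (length(sds) < min_valid_rois) {
    return(tibble::tibble(
      slice = as.integer(slice_index), compartment = compartment,
      mean_gn = NA_real_, mode_gn = NA_real_, n_rois = length(sds),
      reason = sprintf("only %d valid ROIs (< %d)", length(sds), min_valid_rois),
      roi_sds = list(sds)))
  }
  tibble::tibble(
    slice = as.integer(slice_index), compartment = compartment,
    mean_gn = mean(sds), mode_gn = hist_mode(sds, bin_width_hu),
    n_rois = length(sds), reason = NA_character_, roi_sds = list(sds))
}
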