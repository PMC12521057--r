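#' Construct a CT volume
#'
#' An ordered stack of HU-calibrated axial slices with in-plane spacing and
#' slice geometry. Slice index 1 is the most inferior position; axial
#' positions must be strictly monotone ascending. At least two slices are
#' required because the Wisconsin noise metrics subtract adjacent slices.
#'
#' @param slices 3-D numeric array of HU values indexed (slice, row, col).
#' @param pixel_spacing_mm Length-2 positive numeric, (row, col) spacing in mm.
#' @param slice_thickness_mm Positive scalar, nominal slice thickness in mm.
#' @param slice_positions_mm Numeric vector of axial positions, one per slice,
#'   strictly ascending.
#' @param series_id,exam_id Opaque identifiers carried through to results.
#'
#' @return An object of class `"ct_volume"`.
#' @examples
#' v <- ct_volume(array(0, c(2, 8, 8)), c(1, 1), 3, c(0, 3))
#' n_slices(v)
#' @export
ct_volume <- function(slices, pixel_spacing_mm, slice_thickness_mm,
                      slice_positions_mm = seq_len(dim(slices)[1]) * slice_thickness_mm,
                      series_id = "series-1", exam_id = "exam-1") {
  if (!is.array(slices) || length(dim(slices)) != 3) {
    stop("`slices` must be a 3-D array indexed (slice, row, col)", call. = FALSE)
  }
  d <- dim(slices)
  if (d[1] < 2) {
    stop("a CT volume needs >= 2 slices: the Wisconsin metrics subtract each ",
         "slice from its adjacent neighbor", call. = FALSE)
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  stopifnot(length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0),
            length(slice_thickness_mm) == 1, slice_thickness_mm > 0,
            length(slice_positions_mm) == d[1])
  if (any(diff(slice_positions_mm) <= 0)) {
    stop("`slice_positions_mm` must be strictly ascending", call. = FALSE)
  }
  steps <- diff(slice_positions_mm)
  if (d[1] > 2 && diff(range(steps)) > 1e-6 * max(steps)) {
    warning("non-uniform slice spacing; adjacent-slice subtraction uses ",
            "index-adjacent slices", call. = FALSE)
  }
  structure(list(
    slices = slices,
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = as.numeric(slice_thickness_mm),
    slice_positions_mm = as.numeric(slice_positions_mm),
    series_id = as.character(series_id),
    exam_id = as.character(exam_id)
  ), class = "ct_volume")
}

#' @rdname ct_volume
#' @param x A `ct_volume`.
#' @export
n_slices <- function(x) {
  stopifnot(inherits(x, "ct_volume"))
  dim(x$slices)[1]
}

#' Extract one axial slice as a matrix
#'
#' @param x A `ct_volume`.
#' @param i Slice index (1-based, inferior to superior).
#' @return Numeric (row, col) matrix of HU values.
#' @export
get_slice <- function(x, i) {
  stopifnot(inherits(x, "ct_volume"), i >= 1, i <= n_slices(x))
  x$slices[i, , ]
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<ct_volume> exam %s / series %s\n", x$exam_id, x$series_id))
  cat(sprintf("  %d slices of %d x %d px, %.3g x %.3g mm/px, thickness %.3g mm\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  cat(sprintf("  axial positions %.2f .. %.2f mm; HU range [%.1f, %.1f]\n",
              x$slice_positions_mm[1], x$slice_positions_mm[d[1]],
              min(x$slices), max(x$slices)))
  invisible(x)
}
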