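# Slice-to-exam aggregation, best-scan selection for multi-scan exams, and
# classification against CMS noise thresholds.

#' Per-slice global-noise values for all five metrics
#'
#' Runs the Duke soft-tissue mode and the four Wisconsin metrics on every
#' slice of a volume.
#'
#' @param volume A [ct_volume()].
#' @param config A [gn_config()].
#' @return A tibble in long form: `slice`, `metric`, `value` (HU, `NA`
#'   where a slice yields no value), `n_units` (masked pixels for Duke,
#'   valid ROIs for Wisconsin), `reason`.
#' @export
gn_slice_values <- function(volume, config = gn_config()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "gn_config"))
  purrr::map_dfr(seq_len(n_slices(volume)), function(i) {
    duke <- duke_slice_gn(
      get_slice(volume, i), volume$pixel_spacing_mm,
      window_mm = config$duke_window_mm,
      bin_width_hu = config$histogram_bin_hu,
      min_mask_pixels = config$min_mask_pixels,
      tissue_hu_range = config$tissue_hu_range)
    wisc <- purrr::map_dfr(c("tissue", "air"), function(comp) {
      wisconsin_slice_gn(
        volume, i, comp,
        roi_mm = config$wisconsin_roi_mm,
        bin_width_hu = config$histogram_bin_hu,
        sqrt2_correction = config$sqrt2_correction,
        min_valid_rois = config$min_valid_rois,
        median_kernel_px = config$median_kernel_px,
        hu_range = if (comp == "tissue") config$tissue_hu_range else config$air_hu_range,
        exclude_background_air = config$exclude_background_air)
    })
    dplyr::bind_rows(
      tibble::tibble(slice = i, metric = "Duke_tissue_mode",
                     value = as.numeric(duke), n_units = attr(duke, "n"),
                     reason = attr(duke, "reason") %||% NA_character_),
      wisc |>
        tidyr::pivot_longer(c("mean_gn", "mode_gn"), names_to = "summary",
                            values_to = "value") |>
        dplyr::mutate(metric = paste0(
          "Wisconsin_", .data$compartment, "_",
          ifelse(.data$summary == "mean_gn", "mean", "mode"))) |>
        dplyr::select(slice = "slice", "metric", "value",
                      n_units = "n_rois", "reason")
    )
  })
}

#' Exam-level global noise from slice values
#'
#' Arithmetic mean of the slice values that exist; slices without a value
#' are excluded and counted.
#'
#' @param slice_values Numeric vector of per-slice GN values, `NA` for
#'   slices with no value.
#' @return A list: `value` (HU, or `NA` when no slice has a value),
#'   `n_slices_used`, `reason`.
#' @examples
#' exam_gn(c(7, NA, 9))
#' @export
exam_gn <- function(slice_values) {
  ok <- !is.na(slice_values)
  if (!any(ok)) {
    return(list(value = NA_real_, n_slices_used = 0L,
                reason = "no slice produced a value"))
  }
  list(value = mean(slice_values[ok]), n_slices_used = sum(ok), reason = NA_character_)
}

#' Exam-level global noise for all five metrics of one series
#'
#' @param volume A [ct_volume()].
#' @param config A [gn_config()]. With `pool_rois = TRUE` the Wisconsin
#'   metrics pool ROI SDs from all slices into one exam histogram instead
#'   of averaging per-slice summaries.
#' @return A tibble with one row per metric: `exam_id`, `scan_id`,
#'   `metric`, `exam_gn` (HU), `n_slices_used`, `n_slices`.
#' @export
compute_exam_gn <- function(volume, config = gn_config()) {
  sv <- gn_slice_values(volume, config)
  out <- sv |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(res = list(exam_gn(.data$value)), .groups = "drop") |>
    dplyr::mutate(exam_gn = purrr::map_dbl(.data$res, "value"),
                  n_slices_used = purrr::map_int(.data$res, "n_slices_used")) |>
    dplyr::select(-"res")
  if (config$pool_rois) {
    pooled <- pooled_wisconsin_exam_gn(volume, config)
    out <- dplyr::rows_update(out, pooled, by = "metric")
  }
  tibble::tibble(exam_id = volume$exam_id, scan_id = volume$series_id,
                 metric = factor(out$metric, levels = gn_metric_names()),
                 exam_gn = out$exam_gn,
                 n_slices_used = out$n_slices_used,
                 n_slices = n_slices(volume)) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
}

# exam-level Wisconsin summaries over ROI SDs pooled across all slices
pooled_wisconsin_exam_gn <- function(volume, config) {
  purrr::map_dfr(c("tissue", "air"), function(comp) {
    rows <- purrr::map_dfr(seq_len(n_slices(volume)), function(i) {
      wisconsin_slice_gn(
        volume, i, comp, roi_mm = config$wisconsin_roi_mm,
        bin_width_hu = config$histogram_bin_hu,
        sqrt2_correction = config$sqrt2_correction,
        min_valid_rois = 1L, median_kernel_px = config$median_kernel_px,
        hu_range = if (comp == "tissue") config$tissue_hu_range else config$air_hu_range,
        exclude_background_air = config$exclude_background_air)
    })
    sds <- unlist(rows$roi_sds)
    used <- sum(rows$n_rois > 0)
    if (length(sds) < config$min_valid_rois) {
      return(tibble::tibble(metric = paste0("Wisconsin_", comp, c("_mean", "_mode")),
                            exam_gn = NA_real_, n_slices_used = used))
    }
    tibble::tibble(
      metric = paste0("Wisconsin_", comp, c("_mean", "_mode")),
      exam_gn = c(mean(sds), hist_mode(sds, config$histogram_bin_hu)),
      n_slices_used = used)
  })
}

#' Best-scan selection for multi-scan exams
#'
#' An exam with several scans is assigned the best (lowest, i.e. highest
#' quality) global-noise value across scans. Ties keep the first scan in
#' the given order.
#'
#' @param per_scan_exam_values Named numeric vector (names = scan ids) or
#'   a data frame with columns `scan_id` and `exam_gn`.
#' @return A list: `scan_id`, `value`.
#' @examples
#' best_scan_gn(c(A = 20, B = 12))
#' @export
best_scan_gn <- function(per_scan_exam_values) {
  if (is.data.frame(per_scan_exam_values)) {
    v <- per_scan_exam_values$exam_gn
    names(v) <- per_scan_exam_values$scan_id
  } else {
    v <- per_scan_exam_values
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no scan has a global-noise value", call. = FALSE)
  i <- which.min(v)  # first minimum = first scan in series order on ties
  list(scan_id = names(v)[i], value = unname(v[i]))
}

#' CMS noise thresholds by exam category
#'
#' The seven exam categories shipped with the package (renal stone,
#' abdomen/pelvis without contrast, enterography, urogram, renal mass
#' without contrast, chest without contrast, pulmonary embolism) with
#' their CMS noise thresholds in HU. Further categories can be supplied
#' via a user CSV with the same columns.
#'
#' @param path CSV to read; defaults to the bundled table.
#' @return A tibble: `category`, `body_region`, `dose_category`,
#'   `noise_threshold_hu`.
#' @export
cms_thresholds <- function(path = system.file("extdata", "cms_thresholds.csv",
                                              package = "ctgn")) {
  tbl <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("category", "noise_threshold_hu") %in% names(tbl)),
            all(tbl$noise_threshold_hu > 0))
  tbl
}

#' Classify an exam global-noise value against a CMS threshold
#'
#' `"exceeds"` iff the exam GN is strictly above the category threshold;
#' values equal to the threshold are `"within"`.
#'
#' @param exam_gn_hu Exam-level GN (HU); vectorised.
#' @param category Category name present in `thresholds`.
#' @param thresholds Threshold table from [cms_thresholds()].
#' @return Character vector, `"within"` or `"exceeds"` (`NA` in, `NA` out).
#' @examples
#' classify_compliance(c(30, 29), "abdomen_pelvis_wo")
#' @export
classify_compliance <- function(exam_gn_hu, category,
                                thresholds = cms_thresholds()) {
  row <- thresholds[thresholds$category == category, ]
  if (nrow(row) != 1) {
    stop("unknown category '", category, "'; configured: ",
         paste(thresholds$category, collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(exam_gn_hu), NA_character_,
         ifelse(exam_gn_hu > row$noise_threshold_hu, "exceeds", "within"))
}
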