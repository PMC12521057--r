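# Workflow entry points behind the command-line tool: compute GN for a tree
# of DICOM exams, compare a cohort table, simulate phantom cohorts. Every
# output embeds the resolved configuration for auditability.

config_snapshot <- function(config) unclass(config)

#' Compute exam-level GN for a directory tree of DICOM exams
#'
#' Each subdirectory of `input_dir` is treated as one exam (a directory
#' without subdirectories is a single exam). Every series found in an exam
#' directory is computed separately; for multi-series exams each metric is
#' assigned its best (lowest) value across series, recording the winning
#' scan. Unreadable series are skipped with a message.
#'
#' @param input_dir Directory of exam directories (or one exam).
#' @param output_dir Optional; when given, writes `exam_gn.csv`,
#'   `exam_gn_slices.csv` and `report.json` (with the resolved config).
#' @param config A [gn_config()].
#' @param category Optional CMS exam category applied to all exams; adds
#'   compliance flags (`"unknown"` when the category is not configured).
#' @param thresholds See [cms_thresholds()].
#' @return A list: `exams` (wide tibble, one row per exam), `per_scan`
#'   (long tibble, one row per exam/scan/metric), `slices` (per-slice
#'   values), `config`.
#' @export
cmd_compute <- function(input_dir, output_dir = NULL, config = gn_config(),
                        category = NULL, thresholds = cms_thresholds()) {
  subdirs <- list.dirs(input_dir, recursive = FALSE)
  exam_dirs <- if (length(subdirs) == 0) input_dir else subdirs
  exam_dirs <- exam_dirs[vapply(exam_dirs,
                                function(d) length(list.files(d)) > 0, TRUE)]
  if (length(exam_dirs) == 0) stop("no exams found under ", input_dir, call. = FALSE)

  per_scan <- list()
  slices <- list()
  for (d in sort(exam_dirs)) {
    series_tbl <- tryCatch(list_ct_series(d), error = function(e) {
      message("skipping ", d, ": ", conditionMessage(e)); NULL
    })
    if (is.null(series_tbl)) next
    for (uid in series_tbl$series_uid) {
      vol <- tryCatch(load_ct_series(d, series = uid), error = function(e) {
        message("skipping series ", uid, " in ", d, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(vol)) next
      message(sprintf("exam %s / scan %s: %d slices", vol$exam_id,
                      vol$series_id, n_slices(vol)))
      per_scan[[length(per_scan) + 1]] <- compute_exam_gn(vol, config)
      sv <- gn_slice_values(vol, config)
      sv$exam_id <- vol$exam_id
      sv$scan_id <- vol$series_id
      slices[[length(slices) + 1]] <- sv
    }
  }
  if (length(per_scan) == 0) stop("no readable series under ", input_dir, call. = FALSE)
  per_scan <- dplyr::bind_rows(per_scan)
  slices <- dplyr::bind_rows(slices)

  # best (lowest-noise, highest-quality) scan per exam and metric
  best <- per_scan |>
    dplyr::group_by(.data$exam_id, .data$metric) |>
    dplyr::group_modify(function(g, key) {
      if (all(is.na(g$exam_gn))) {
        return(tibble::tibble(scan_id = g$scan_id[1], exam_gn = NA_real_,
                              n_slices_used = 0L))
      }
      b <- best_scan_gn(g)
      tibble::tibble(scan_id = b$scan_id, exam_gn = b$value,
                     n_slices_used = g$n_slices_used[g$scan_id == b$scan_id])
    }) |>
    dplyr::ungroup()

  if (!is.null(category)) {
    best$compliance <- if (category %in% thresholds$category) {
      classify_compliance(best$exam_gn, category, thresholds)
    } else {
      warning("category '", category, "' not in the threshold table; ",
              "compliance is 'unknown'", call. = FALSE)
      "unknown"
    }
    best$category <- category
  }
  wide <- best |>
    tidyr::pivot_wider(id_cols = "exam_id", names_from = "metric",
                       values_from = c("exam_gn", "scan_id", "n_slices_used",
                                       if (!is.null(category)) "compliance"),
                       names_glue = "{metric}_{.value}")
  names(wide) <- sub("_exam_gn$", "", names(wide))
  if (!is.null(category)) wide$category <- category

  out <- list(exams = wide, per_scan = per_scan, slices = slices,
              config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(wide, file.path(output_dir, "exam_gn.csv"), row.names = FALSE)
    write.csv(slices[c("exam_id", "scan_id", "slice", "metric", "value",
                       "n_units")],
              file.path(output_dir, "exam_gn_slices.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = config_snapshot(config),
           category = category,
           n_exams = nrow(wide),
           exams = wide),
      file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  out
}

#' Compare a cohort CSV of exam-level GN values
#'
#' @param cohort_csv CSV with one row per exam and one column per metric
#'   (e.g. `exam_gn.csv` from [cmd_compute()], or any exams-by-metrics
#'   table).
#' @param slice_csv Optional CSV of slice-level records (`exam_id`,
#'   `slice`, `metric`, `value`) enabling the per-exam permutation tests;
#'   when absent that section is omitted with a notice.
#' @param output_dir Optional; writes `comparison.json`,
#'   `pairwise.csv` and, when graphics are available, box-plot and
#'   heatmap figures.
#' @param alpha,n_perm,seed See [gn_compare()].
#' @param category Optional CMS category for the box-plot threshold line.
#' @return The `"gn_comparison"` object.
#' @export
cmd_compare <- function(cohort_csv, slice_csv = NULL, output_dir = NULL,
                        alpha = 0.05, n_perm = 10000, seed = 1L,
                        category = NULL) {
  cohort <- read.csv(cohort_csv, stringsAsFactors = FALSE)
  if (nrow(cohort) < 3) stop("need >= 3 exams to compare", call. = FALSE)
  slice_values <- NULL
  if (!is.null(slice_csv)) {
    slice_values <- read.csv(slice_csv, stringsAsFactors = FALSE)
  } else {
    message("no slice-level CSV given; permutation tests omitted")
  }
  cmp <- gn_compare(cohort, slice_values = slice_values, alpha = alpha,
                    n_perm = n_perm, seed = seed)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tidy(cmp), file.path(output_dir, "pairwise.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(settings = list(alpha = alpha, n_perm = n_perm, seed = seed),
           friedman = cmp$friedman,
           pairwise = cmp$pairwise,
           pearson = list(r = cmp$pearson$r, labels = cmp$pearson$labels),
           permutation = cmp$permutation),
      file.path(output_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    try({
      ggplot2::ggsave(file.path(output_dir, "gn_boxplot.png"),
                      plot_gn_box(cohort, category = category),
                      width = 7, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(output_dir, "gn_heatmap.png"),
                      plot_gn_heatmap(cmp), width = 7, height = 6, dpi = 150)
    }, silent = TRUE)
  }
  cmp
}

#' Simulate a phantom cohort from a JSON spec
#'
#' The spec file is a JSON object; recognised fields are the arguments of
#' [phantom_spec()] plus `n_exams`, `sigma_distribution` and `seed`.
#'
#' @param spec_file Path to the JSON spec.
#' @param output_dir Directory for the DICOM series, ground-truth CSV and
#'   manifest.
#' @return The [make_cohort()] result, invisibly.
#' @export
cmd_simulate <- function(spec_file, output_dir) {
  raw <- jsonlite::read_json(spec_file, simplifyVector = TRUE)
  known <- names(formals(phantom_spec))
  extra <- setdiff(names(raw), c(known, "n_exams", "sigma_distribution"))
  if (length(extra) > 0) {
    stop("unknown spec field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  sp <- do.call(phantom_spec, raw[intersect(names(raw), known)])
  n_exams <- raw$n_exams %||% 1
  sigma_distribution <- raw$sigma_distribution %||%
    list(type = "constant", value = sp$sigma_hu)
  if (is.data.frame(sigma_distribution)) {
    sigma_distribution <- as.list(sigma_distribution)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(make_cohort(sp, n_exams = n_exams,
                        sigma_distribution = sigma_distribution,
                        seed = sp$seed, dir = output_dir))
}
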