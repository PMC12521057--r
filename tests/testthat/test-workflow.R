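write_sim_spec <- function(path, n_exams = 3, shape = c(2, 64, 64),
                           sigma = 10, seed = 3) {
  fov <- min(shape[2:3]) * 0.7
  jsonlite::write_json(list(
    shape = shape, sigma_hu = sigma, seed = seed, n_exams = n_exams,
    body_axes_mm = c(0.7 * fov, 0.5 * fov),
    sigma_distribution = list(type = "constant", value = sigma)),
    path, auto_unbox = TRUE)
  path
}

test_that("simulate -> compute -> compare runs end to end", {
  root <- withr::local_tempdir()
  spec <- write_sim_spec(file.path(root, "spec.json"), n_exams = 3)
  sim_dir <- file.path(root, "sim")
  cmd_simulate(spec, sim_dir)
  expect_length(list.dirs(sim_dir, recursive = FALSE), 3)

  out <- file.path(root, "gn")
  res <- cmd_compute(sim_dir, out, category = "abdomen_pelvis_wo")
  expect_equal(nrow(res$exams), 3)
  expect_true(all(gn_metric_names() %in% names(res$exams)))
  expect_true(file.exists(file.path(out, "exam_gn.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(rep$config$wisconsin_roi_mm, 7)  # resolved config embedded
  expect_equal(rep$category, "abdomen_pelvis_wo")

  cmp_dir <- file.path(root, "cmp")
  cmp <- cmd_compare(file.path(out, "exam_gn.csv"),
                     slice_csv = file.path(out, "exam_gn_slices.csv"),
                     output_dir = cmp_dir, n_perm = 200, seed = 4)
  expect_s3_class(cmp, "gn_comparison")
  expect_true(file.exists(file.path(cmp_dir, "comparison.json")))
  expect_true(file.exists(file.path(cmp_dir, "pairwise.csv")))
  expect_false(is.null(cmp$permutation))
})

test_that("multi-series exams route through best-scan selection", {
  root <- withr::local_tempdir()
  exam <- file.path(root, "exam-1")
  smooth <- make_phantom(small_spec(shape = c(2, 96, 96), sigma_hu = 10,
                                    seed = 19, kernel_fwhm_mm = 2,
                                    rescale_noise = FALSE),
                         exam_id = "exam-1", series_id = "smooth")$volume
  sharp <- make_phantom(small_spec(shape = c(2, 96, 96), sigma_hu = 10,
                                   seed = 20),
                        exam_id = "exam-1", series_id = "sharp")$volume
  write_ct_series(smooth, exam)
  write_ct_series(sharp, exam)
  res <- cmd_compute(root)
  expect_equal(nrow(res$exams), 1)
  expect_equal(nrow(res$per_scan), 10)  # 2 scans x 5 metrics
  expect_equal(unname(res$exams$Duke_tissue_mode_scan_id), "smooth")
  expect_lt(res$exams$Duke_tissue_mode,
            min(res$per_scan$exam_gn[res$per_scan$scan_id == "sharp"]))
})

test_that("an unconfigured category degrades to compliance 'unknown'", {
  root <- withr::local_tempdir()
  co <- make_cohort(small_spec(shape = c(2, 64, 64)), 1,
                    list(type = "constant", value = 10), seed = 1,
                    dir = file.path(root, "sim"))
  expect_warning(
    res <- cmd_compute(file.path(root, "sim"), category = "cardiac"),
    "unknown")
  expect_true(all(res$exams$category == "cardiac"))
  expect_true(all(grepl("unknown",
                        unlist(res$exams[grepl("compliance", names(res$exams))]))))
})

test_that("compare without slice records omits permutation with a notice", {
  root <- withr::local_tempdir()
  cohort <- tibble::tibble(exam_id = sprintf("e%d", 1:6),
                           Duke_tissue_mode = c(10, 11, 12, 13, 14, 15),
                           Wisconsin_tissue_mean = c(12, 13, 15, 15, 17, 18))
  f <- file.path(root, "cohort.csv")
  write.csv(cohort, f, row.names = FALSE)
  expect_message(cmp <- cmd_compare(f), "omitted")
  expect_null(cmp$permutation)
  expect_error(cmd_compare(f, output_dir = NULL, alpha = 0.05), NA)
  # fewer than three exams is a hard error
  f2 <- file.path(root, "tiny.csv")
  write.csv(cohort[1:2, ], f2, row.names = FALSE)
  expect_error(suppressMessages(cmd_compare(f2)), ">= 3")
})

test_that("malformed simulation specs name the offending field", {
  root <- withr::local_tempdir()
  bad <- file.path(root, "bad.json")
  jsonlite::write_json(list(shape = c(2, 32, 32), wobble = 3), bad,
                       auto_unbox = TRUE)
  expect_error(cmd_simulate(bad, file.path(root, "out")), "wobble")
})

test_that("plot builders return ggplot objects", {
  set.seed(10)
  cohort <- tibble::tibble(Duke_tissue_mode = rnorm(10, 14),
                           Wisconsin_tissue_mean = rnorm(10, 19),
                           Wisconsin_tissue_mode = rnorm(10, 16))
  expect_s3_class(plot_gn_box(cohort, category = "chest_wo"), "ggplot")
  cmp <- gn_compare(cohort)
  expect_s3_class(plot_gn_heatmap(cmp), "ggplot")
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})
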