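test_that("adjacent-slice subtraction pairs every slice once", {
  arr <- array(0, c(3, 8, 8))
  arr[1, , ] <- 10; arr[2, , ] <- 4; arr[3, , ] <- 4
  v <- ct_volume(arr, c(1, 1), 3, c(0, 3, 6))
  d1 <- subtract_adjacent(v, 1)
  expect_true(all(d1 == 6))
  expect_equal(attr(d1, "pair"), c(1L, 2L))
  d2 <- subtract_adjacent(v, 2)
  expect_true(all(d2 == 0))  # identical neighbours cancel
  d3 <- subtract_adjacent(v, 3)  # last slice pairs with the previous one
  expect_equal(attr(d3, "pair"), c(3L, 2L))
  expect_true(all(d3 == 0))
})

test_that("difference of independent equal-noise slices has SD sigma*sqrt(2)", {
  set.seed(8)
  arr <- array(rnorm(2 * 200 * 200, sd = 10), c(2, 200, 200))
  v <- ct_volume(arr, c(1, 1), 3, c(0, 3))
  d <- subtract_adjacent(v, 1)
  expect_lt(abs(sd(d) - 10 * sqrt(2)) / (10 * sqrt(2)), 0.05)
})

test_that("ROI grids tile the slice uniformly from the origin", {
  g <- build_roi_grid(c(512, 512), 7, 0.7)
  expect_equal(g$roi_px, 10L)
  expect_equal(nrow(g$origins), 51L * 51L)
  expect_equal(min(g$origins$row), 1L)
  expect_equal(max(g$origins$row), 501L)  # 51st ROI ends at 510; 511-512 dropped

  g2 <- build_roi_grid(c(100, 100), 7, 1.0)
  expect_equal(g2$roi_px, 7L)
  expect_equal(nrow(g2$origins), 14L * 14L)

  expect_error(build_roi_grid(c(100, 100), 7, 10), "< 2 px")
  expect_error(build_roi_grid(c(10, 10), 70, 1), "exceeds")
})

test_that("zero difference images give zero Wisconsin noise", {
  arr <- array(0, c(2, 70, 70))
  arr[, 20:50, 20:50] <- 50  # identical slices: difference cancels
  v <- ct_volume(arr, c(1, 1), 3, c(0, 3))
  w <- wisconsin_slice_gn(v, 1, "tissue", roi_mm = 7)
  expect_equal(w$mean_gn, 0)
  expect_equal(w$mode_gn, 0)
  expect_gt(w$n_rois, 0)
})

test_that("slices without a fully-contained ROI yield no value", {
  arr <- array(-1000, c(2, 40, 40))
  arr[, 18:22, 18:22] <- 50  # tissue patch smaller than one 7 px ROI
  v <- ct_volume(arr, c(1, 1), 3, c(0, 3))
  w <- wisconsin_slice_gn(v, 1, "tissue", roi_mm = 7)
  expect_true(is.na(w$mean_gn))
  expect_match(w$reason, "valid ROIs")
})

test_that("Wisconsin recovers phantom noise, with and without sqrt(2) correction", {
  p <- small_phantom(shape = c(2, 220, 220), sigma_hu = 10, seed = 17)
  won <- wisconsin_slice_gn(p$volume, 1, "tissue")
  expect_lt(abs(won$mean_gn - 10) / 10, 0.10)
  expect_lt(abs(won$mode_gn - 10) / 10, 0.10)
  woff <- wisconsin_slice_gn(p$volume, 1, "tissue", sqrt2_correction = FALSE)
  expect_lt(abs(woff$mean_gn - 10 * sqrt(2)) / (10 * sqrt(2)), 0.10)
  expect_equal(woff$mean_gn, won$mean_gn * sqrt(2))
})

test_that("tissue and air compartments agree under identical noise", {
  p <- small_phantom(shape = c(2, 220, 220), sigma_hu = 10, seed = 23)
  wt <- wisconsin_slice_gn(p$volume, 1, "tissue")
  wa <- wisconsin_slice_gn(p$volume, 1, "air")
  expect_lt(abs(wt$mean_gn - wa$mean_gn) / wa$mean_gn, 0.10)
})

test_that("shrinking the mask never adds valid ROIs", {
  p <- small_phantom(shape = c(2, 96, 96), sigma_hu = 10, seed = 3)
  diff_img <- subtract_adjacent(p$volume, 1)
  g <- build_roi_grid(dim(diff_img), 7, 0.7)
  full <- make_mask(get_slice(p$volume, 1), "tissue", use_median_filter = TRUE)
  shrunk <- full
  shrunk[1:48, ] <- FALSE
  sd_full <- ctgn:::roi_sd_cpp(diff_img, full, g$origins$row, g$origins$col, g$roi_px)
  sd_shrunk <- ctgn:::roi_sd_cpp(diff_img, shrunk, g$origins$row, g$origins$col, g$roi_px)
  expect_true(all(is.na(sd_shrunk[is.na(sd_full)])))
  same <- !is.na(sd_shrunk)
  expect_identical(sd_shrunk[same], sd_full[same])
})

test_that("identical structure in adjacent slices leaves Wisconsin unchanged", {
  ins <- list(list(shape = "disc", hu = 60, center_mm = c(8, 4), size_mm = 8))
  w0 <- wisconsin_slice_gn(small_phantom(shape = c(2, 128, 128), seed = 5)$volume,
                           1, "tissue")
  w1 <- wisconsin_slice_gn(small_phantom(shape = c(2, 128, 128), seed = 5,
                                         inserts = ins)$volume,
                           1, "tissue")
  expect_identical(w1$mean_gn, w0$mean_gn)
  expect_identical(w1$mode_gn, w0$mode_gn)
  expect_identical(w1$n_rois, w0$n_rois)
})

test_that("mean lies inside the ROI SD range and the mode inside the support", {
  p <- small_phantom(shape = c(2, 128, 128), sigma_hu = 12, seed = 9)
  w <- wisconsin_slice_gn(p$volume, 1, "tissue")
  sds <- w$roi_sds[[1]]
  expect_gte(w$mean_gn, min(sds))
  expect_lte(w$mean_gn, max(sds))
  expect_gte(w$mode_gn, min(sds) - 0.5)
  expect_lte(w$mode_gn, max(sds) + 0.5)
  # edge-containing masks skew the mean above the mode
  expect_gte(w$mean_gn, w$mode_gn - 0.5)
})
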