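test_that("HMR of synthetic two-level and uniform images is exact", {
  img <- structure(matrix(100L, 80, 80), pixel_size_mm = 4.75)
  rois <- roi_set(20, 20, 6, 50, 50, 10, 10, dim = c(80, 80))
  expect_equal(compute_hmr(img, rois)$hmr, 1.0)

  two <- matrix(100L, 80, 80)
  hm <- mibgcal:::disc_mask(c(80, 80), 21, 21, 6)
  two[hm] <- 200L
  two <- structure(two, pixel_size_mm = 4.75)
  expect_equal(compute_hmr(two, rois)$hmr, 2.0)
})

test_that("HMR is invariant to global count rescaling", {
  img <- fx_ideal_image("anterior", 128)
  rois <- auto_roi_phantom(img, "anterior")
  h1 <- compute_hmr(img, rois)$hmr
  scaled <- structure(unclass(img) * 7L,
    pixel_size_mm = attr(img, "pixel_size_mm")
  )
  expect_equal(compute_hmr(scaled, rois)$hmr, h1, tolerance = 1e-12)
})

test_that("auto ROIs land inside the generating compartments", {
  for (view in c("anterior", "posterior")) {
    img <- fx_ideal_image(view)
    masks <- attr(fx_phantom(view), "masks")
    rois <- auto_roi_phantom(img, view)
    expect_true(masks$heart[rois$heart$row + 1L, rois$heart$col + 1L])
    roim <- mibgcal:::roi_set_masks(rois)
    expect_true(all(masks$mediastinum[roim$mediastinum]))
    expect_gte(rois$heart$n_px, 20L)
    expect_gte(rois$mediastinum$n_px, 20L)
  }
})

test_that("heart ROI radius perturbations of 10% change HMR by under 2%", {
  img <- fx_ideal_image("anterior")
  base <- measure_hmr(img, "anterior", heart_radius_mm = 25)$hmr
  lo <- measure_hmr(img, "anterior", heart_radius_mm = 22.5)$hmr
  hi <- measure_hmr(img, "anterior", heart_radius_mm = 27.5)$hmr
  expect_lt(abs(lo - base) / base, 0.02)
  expect_lt(abs(hi - base) / base, 0.02)
})

test_that("a 15 mm translation changes the automatically measured HMR by under 1%", {
  img <- fx_ideal_image("anterior")
  n <- nrow(img)
  px <- attr(img, "pixel_size_mm")
  sh <- as.integer(round(15 / px))
  shifted <- matrix(0L, n, n)
  shifted[(1 + sh):n, (1 + sh):n] <- unclass(img)[1:(n - sh), 1:(n - sh)]
  shifted <- structure(shifted, pixel_size_mm = px)
  h0 <- measure_hmr(img, "anterior")$hmr
  h1 <- measure_hmr(shifted, "anterior")$hmr
  expect_lt(abs(h1 - h0) / h0, 0.01)
})

test_that("unusable images are rejected with a clear error", {
  zero <- structure(matrix(0L, 64, 64), pixel_size_mm = 5.9)
  expect_error(auto_roi_phantom(zero, "anterior"), "uniform or empty")
  flat <- structure(matrix(7L, 64, 64), pixel_size_mm = 5.9)
  expect_error(auto_roi_phantom(flat, "anterior"), "uniform or empty")
})

test_that("ROI sets enforce their invariants", {
  expect_error(roi_set(3, 3, 6, 40, 40, 8, 8, dim = c(64, 64)), "outside")
  expect_error(roi_set(20, 20, 6, 60, 60, 10, 10, dim = c(64, 64)), "outside")
  expect_error(roi_set(20, 20, 6, 22, 22, 10, 10, dim = c(64, 64)), "disjoint")
  expect_error(roi_set(20, 20, 2, 40, 40, 10, 10, dim = c(64, 64)), "20 pixels")
  rois <- roi_set(20, 20, 6, 40, 40, 10, 10, dim = c(64, 64))
  img <- structure(matrix(1L, 32, 32), pixel_size_mm = 5.9)
  expect_error(compute_hmr(img, rois), "dimensions")
})

test_that("zero mediastinal counts cannot form a ratio", {
  img <- matrix(0L, 64, 64)
  img[mibgcal:::disc_mask(c(64, 64), 21, 21, 6)] <- 50L
  img <- structure(img, pixel_size_mm = 5.9)
  rois <- roi_set(20, 20, 6, 40, 40, 10, 10, dim = c(64, 64))
  expect_error(compute_hmr(img, rois), "zero")
})

test_that("heart template ties break to the smallest row, then column", {
  img <- matrix(10L, 90, 90)
  # two identical hot discs; detection must pick the upper-left one
  img[mibgcal:::disc_mask(c(90, 90), 25, 25, 10)] <- 100L
  img[mibgcal:::disc_mask(c(90, 90), 60, 35, 10)] <- 100L
  img <- structure(img, pixel_size_mm = 380 / 90)
  rois <- auto_roi_phantom(img, "anterior", heart_radius_mm = 6 * 380 / 90)
  expect_lt(rois$heart$row, 30)
  expect_lt(rois$heart$col, 30)
})

test_that("tidy() exposes the HMR result as a one-row tibble", {
  res <- measure_hmr(fx_ideal_image("anterior", 128), "anterior")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$hmr, res$hmr)
})
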