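test_that("geometric FWHM follows the parallel-hole resolution model", {
  # with mu159 = 2.3/mm, L = 40 + 2/2.3 gives L_eff = 40 exactly
  col <- collimator_spec(2, 0.3, 40 + 2 / 2.3)
  expect_equal(geometric_fwhm(col, 0), 2.0, tolerance = 1e-12) # FWHM = d at the face
  expect_equal(geometric_fwhm(col, 40), 4.0, tolerance = 1e-12) # doubles at z = L_eff
  # hand arithmetic: L_eff = 35 - 2/2.3 = 34.130435;
  # 1.5 * (134.130435 / 34.130435) = 5.894904
  col2 <- collimator_spec(1.5, 0.3, 35)
  expect_equal(geometric_fwhm(col2, 100), 5.894904, tolerance = 1e-6)
  # strictly increasing in distance
  d <- geometric_fwhm(col2, c(0, 10, 50, 100, 180))
  expect_true(all(diff(d) > 0))
  expect_error(geometric_fwhm(col2, -5), ">= 0")
})

test_that("collimator spec validates its ranges", {
  expect_error(collimator_spec(0.2, 0.3, 40), "hole diameter")
  expect_error(collimator_spec(2, 3, 40), "septal")
  expect_error(collimator_spec(2, 0.3, 5), "length")
  expect_error(collimator_spec(2, 0.3, 40, mu159_mm = -1), "attenuation")
})

test_that("penetration fraction: limits, LEHR vs MEGP ordering, monotonicity", {
  # thick long septa absorb essentially all 529 keV photons
  expect_lt(penetration_fraction(collimator_spec(0.5, 2, 80)), 1e-4)
  # low-energy collimators leak more than medium-energy ones
  lehr <- collimator_spec(1.11, 0.16, 24.05)
  megp <- collimator_spec(2.94, 1.14, 48)
  expect_gt(penetration_fraction(lehr), penetration_fraction(megp))
  # monotone in each design parameter and in window width
  f_d <- vapply(1:5, function(d) penetration_fraction(collimator_spec(d, 0.5, 40)), 0)
  f_t <- vapply(seq(0.1, 1.5, 0.35), function(t) penetration_fraction(collimator_spec(2, t, 40)), 0)
  f_L <- vapply(seq(20, 60, 10), function(L) penetration_fraction(collimator_spec(2, 0.5, L)), 0)
  expect_true(all(diff(f_d) > 0))
  expect_true(all(diff(f_t) < 0))
  expect_true(all(diff(f_L) < 0))
  expect_gt(
    penetration_fraction(lehr, 10),
    penetration_fraction(lehr, 7.5)
  )
  expect_true(all(f_d >= 0 & f_d <= 1))
})

test_that("noise-free simulation conserves total counts to within 0.1%", {
  amap <- fx_phantom("anterior", 128)
  st <- acquisition_settings(matrix = 128) # 55.5 MBq x 300 s -> 1e6 counts
  for (col in list(ideal_collimator(), collimator_spec(1.11, 0.16, 24.05), collimator_spec(2.94, 1.14, 48))) {
    img <- simulate_planar(amap, col, st, noise = FALSE)
    expect_equal(sum(as.numeric(img)), 1e6, tolerance = 1e-3)
    expect_true(all(img >= 0))
    expect_true(is.integer(unclass(img)))
  }
})

test_that("zero activity yields an all-zero image; empty map errors", {
  zero <- build_phantom(380 / 128, "anterior", densities = c(
    heart = 0, mediastinum = 0, liver = 0, lungs = 0, thyroid = 0, background = 0
  ))
  img <- simulate_planar(zero, ideal_collimator(), acquisition_settings(matrix = 128), noise = FALSE)
  expect_true(all(img == 0L))
})

test_that("Poisson noise is reproducible under a seed and leaves ambient RNG alone", {
  amap <- fx_phantom("anterior", 128)
  st <- acquisition_settings(matrix = 128, seed = 11)
  set.seed(999)
  before <- .Random.seed
  i1 <- simulate_planar(amap, collimator_spec(2, 0.9, 40), st)
  expect_identical(.Random.seed, before) # caller RNG restored
  i2 <- simulate_planar(amap, collimator_spec(2, 0.9, 40), st)
  expect_identical(unclass(i1), unclass(i2))
  st2 <- acquisition_settings(matrix = 128, seed = 12)
  i3 <- simulate_planar(amap, collimator_spec(2, 0.9, 40), st2)
  expect_false(identical(unclass(i1), unclass(i3)))
})

test_that("ideal-system imaging reproduces the designated HMR", {
  for (view in c("anterior", "posterior")) {
    h <- measure_hmr(fx_ideal_image(view), view)$hmr
    expect_equal(h, designated_hmr(view), tolerance = 0.01 / designated_hmr(view))
  }
})

test_that("LEHR-like systems measure lower HMR than MEGP-like systems", {
  amap <- fx_phantom("anterior")
  st <- quiet_settings()
  h_lehr <- measure_hmr(simulate_planar(amap, collimator_spec(1.11, 0.16, 24.05), st, noise = FALSE), "anterior")$hmr
  h_megp <- measure_hmr(simulate_planar(amap, collimator_spec(2.94, 1.14, 48), st, noise = FALSE), "anterior")$hmr
  expect_lt(h_lehr, h_megp)
  expect_lt(h_megp, designated_hmr("anterior")) # blur+penetration always degrade
})

test_that("single-point sweep returns one ordered row per grid point", {
  amap <- fx_phantom("anterior", 128)
  st <- acquisition_settings(matrix = 128, window_halfwidth_pct = 7.5, duration_s = 30000)
  one <- sweep_collimator_designs(amap, 2, 0.5, 40, settings = st)
  expect_equal(nrow(one), 1L)
  expect_true(all(c("hole_diameter_mm", "septal_thickness_mm", "length_mm", "hmr") %in% names(one)))
  small <- sweep_collimator_designs(amap, c(3, 1), c(0.8, 0.2), c(50, 30), settings = st)
  expect_equal(nrow(small), 8L)
  # ordered by (L, t, d)
  expect_equal(small$length_mm, rep(c(30, 50), each = 4))
  expect_equal(small$septal_thickness_mm, rep(rep(c(0.2, 0.8), each = 2), 2))
  expect_equal(small$hole_diameter_mm, rep(c(1, 3), 4))
  expect_error(sweep_collimator_designs(amap, numeric(0), 0.5, 40), "nonempty")
})

test_that("acquisition settings validate their domains", {
  expect_error(acquisition_settings(matrix = 100), "matrix")
  expect_error(acquisition_settings(duration_s = 0), "duration")
  expect_error(acquisition_settings(distance_mm = -1), "distance")
  expect_error(acquisition_settings(window_halfwidth_pct = 0), "half-width")
})
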