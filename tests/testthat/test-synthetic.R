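test_that("generated databases are deterministic under a seed", {
  d1 <- generate_database(synth_db_spec(), seed = 5)
  d2 <- generate_database(synth_db_spec(), seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_database(synth_db_spec(), seed = 6)
  expect_false(identical(d1, d3))
})

test_that("default database carries the documented strata", {
  db <- generate_database(synth_db_spec(), seed = 2)
  expect_equal(nrow(db), 1648L)
  expect_equal(sum(db$planted_stratum == "minor_energy_window"), 297L)
  expect_equal(sum(db$planted_stratum == "scatter_correction"), 145L)
  expect_equal(sum(db$planted_stratum == "minor_collimator_or_camera"), 14L)
  expect_equal(sum(db$planted_stratum == "eligible"), 705L)
  # missing-window records exist (n = 4 in the breakdown)
  expect_equal(sum(is.na(db$window_center_kev)), 4L)
})

test_that("planted conversion coefficients back-solve exactly through the calibration formula", {
  db <- generate_database(synth_db_spec(), seed = 8)
  cc <- conversion_coefficient(db$hmr_ant[1], db$hmr_post[1])$value
  expect_equal(cc, db$cc[1], tolerance = 1e-12)
  vec <- mibgcal:::cc_from_hmr(db$hmr_ant, db$hmr_post)
  expect_lt(max(abs(vec - db$cc)), 1e-12)
})

test_that("planted outliers, and only they, are flagged across 20 seeds", {
  for (s in 1:20) {
    db <- generate_database(synth_db_spec(), seed = s)
    qc <- qc_filter(db)
    flagged <- qc$records$record_id[!is.na(qc$records$exclusion_reason) &
      qc$records$exclusion_reason == "cc_outlier"]
    planted <- db$record_id[db$planted_stratum == "cc_outlier"]
    expect_identical(sort(flagged), sort(planted))
  }
})

test_that("inconsistent specs are rejected", {
  spec <- synth_db_spec()
  spec$total <- spec$total + 1
  expect_error(generate_database(spec), "inconsistent spec")
  expect_error(synth_db_spec(group_cc = tibble::tibble(
    group = "LEHR", mean = 0.5, sd = 0, n = 10L
  )), "SD")
})

test_that("group samples recover their generating mean and respect bounds", {
  x <- generate_group_samples("MEGP", 179, 0.879, 0.0429, seed = 21)
  expect_length(x, 179)
  expect_lt(abs(mean(x) - 0.879), 3 * 0.0429 / sqrt(179))
  expect_true(all(x > 0 & x < 1.2))
  expect_identical(attr(x, "group"), "MEGP")
  # degenerate spread collapses to the mean; single draws work
  expect_equal(as.numeric(generate_group_samples("CHR", 5, 0.545, 0, seed = 1)), rep(0.545, 5))
  expect_length(generate_group_samples("CHR", 1, 0.545, 0.02, seed = 1), 1)
  expect_error(generate_group_samples("CHR", 0, 0.5, 0.01), "n must be")
})

test_that("clinical sets have two images per subject and plant the requested layout", {
  scans <- generate_clinical_set(12, 21, c(A = 0.631, B = 0.840), seed = 4)
  expect_equal(nrow(scans), 66L)
  expect_true(all(table(scans$subject_id) == 2))
  expect_setequal(unique(scans$phase), c("early", "delayed"))
  rt <- reclassification_table(scans)
  expect_equal(rt$up, c(4L, 1L))
  expect_equal(rt$down, c(0L, 0L))
  expect_equal(rt$n, c(24L, 42L))
})

test_that("clinical generator handles degenerate and identity cases", {
  expect_equal(nrow(generate_clinical_set(0, 0, c(A = 0.7), seed = 1)), 0L)
  # all-reference hospitals: standardization is the identity
  scans <- generate_clinical_set(6, 6, c(A = 0.88, B = 0.88),
    layout = "random", seed = 9
  )
  expect_equal(standardize_hmr(scans$hmr, scans$cc_i), scans$hmr, tolerance = 1e-12)
  # planting upward moves is impossible when every cc is below the bound
  expect_error(
    generate_clinical_set(12, 21, c(A = 0.5, B = 0.6), seed = 1),
    "cannot plant"
  )
})

test_that("clinical generator is deterministic under a seed", {
  s1 <- generate_clinical_set(seed = 33)
  s2 <- generate_clinical_set(seed = 33)
  expect_identical(s1, s2)
})
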