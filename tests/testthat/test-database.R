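test_that("collimator names map to their groups; minor equipment is excluded", {
  expect_identical(classify_collimator("LEAP", "GE"), "LEGP")
  expect_identical(classify_collimator("LEGAP", "Toshiba"), "LEGP")
  expect_identical(classify_collimator("ME", "Siemens"), "MEGP")
  expect_identical(classify_collimator("MEGAP", "GE"), "MEGP")
  expect_identical(classify_collimator("lehr", "GE"), "LEHR") # case-insensitive
  # minor equipment excluded silently
  expect_identical(classify_collimator("MEHR", "Toshiba"), "excluded")
  expect_identical(classify_collimator("MEDIUM", "Siemens"), "excluded")
  expect_identical(classify_collimator("HEGP", "GE"), "excluded")
  expect_identical(classify_collimator("LEGP", "Hitachi"), "excluded")
  # same name, different vendor: MEDIUM is only minor for Siemens
  expect_warning(out <- classify_collimator("MEDIUM", "GE"), "unrecognized")
  expect_identical(out, "excluded")
  expect_warning(out2 <- classify_collimator("", "GE"), "unrecognized")
  expect_identical(out2, "excluded")
})

test_that("energy-window dialects parse to the same numbers", {
  p <- parse_energy_window(c("159 ± 10%", "159keV±10%", "159:10", "158 k ± 7%", "garbage", NA))
  expect_equal(p$center_kev, c(159, 159, 159, 158, NA, NA))
  expect_equal(p$halfwidth_pct, c(10, 10, 10, 7, NA, NA))
})

test_that("minor energy windows: only 159 +/- 10% and 159 +/- 7.5% are primary", {
  expect_false(is_minor_energy_window(159, 10))
  expect_false(is_minor_energy_window(159, 7.5))
  expect_true(is_minor_energy_window(158, 10))
  expect_true(is_minor_energy_window(160, 7.5))
  expect_true(is_minor_energy_window(159, 12))
  expect_true(is_minor_energy_window(NA, NA))
  expect_true(is_minor_energy_window("missing text"))
})

test_that("Tukey fences flag exactly the planted member (hand-checked)", {
  # sorted {0.53, 0.54, 0.55, 0.56, 0.90}: Q1 = 0.54, Q3 = 0.56 (type-7),
  # fences [0.51, 0.59] -> only 0.90 is out
  rec <- tibble::tibble(cc = c(0.53, 0.55, 0.56, 0.54, 0.90), collimator_group = "LEHR")
  expect_identical(detect_cc_outliers(rec), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # identical values: no flags
  same <- tibble::tibble(cc = rep(0.7, 6), collimator_group = "MEGP")
  expect_false(any(detect_cc_outliers(same)))
  # below minimum group size: no flags
  three <- tibble::tibble(cc = c(0.5, 0.55, 5.0), collimator_group = "LEHR")
  expect_false(any(detect_cc_outliers(three)))
})

test_that("filter applies rules in order: first matching rule wins", {
  rec <- toy_records(
    list(scatter_correction = "dual-window", matrix = 64L), # both 1 and 2 -> rule 1
    list(matrix = 128L, window_center_kev = 158), # both 2 and 3 -> rule 2
    list(window_halfwidth_pct = 12, collimator = "MEHR", vendor = "Toshiba"), # 3 before 4
    list(collimator = "Cardio", vendor = "Toshiba", failed = TRUE), # 4 before 5
    list(failed = TRUE),
    list() # clean record
  )
  qc <- qc_filter(rec)
  expect_identical(
    qc$records$exclusion_reason,
    c(
      "scatter_correction", "small_matrix", "minor_energy_window",
      "minor_collimator_or_camera", "failed_experiment", NA
    )
  )
  expect_equal(nrow(qc$eligible), 1L)
})

test_that("the 7.5% window rule is controlled by include_75_window", {
  rec <- toy_records(
    list(window_halfwidth_pct = 7.5),
    list()
  )
  expect_equal(nrow(qc_filter(rec, include_75_window = FALSE)$eligible), 1L)
  expect_equal(nrow(qc_filter(rec, include_75_window = TRUE)$eligible), 2L)
})

test_that("tally conservation holds exactly on arbitrary record sets", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    rec <- tibble::tibble(
      institution = "X", vendor = sample(c("GE", "Siemens", "Toshiba", "Hitachi"), n, TRUE),
      camera = "cam",
      collimator = sample(c("LEHR", "MEGP", "LMEGP", "MEHR", "???"), n, TRUE),
      window_center_kev = sample(c(159, 158, NA), n, TRUE, prob = c(0.7, 0.2, 0.1)),
      window_halfwidth_pct = sample(c(10, 7.5, 12), n, TRUE),
      matrix = sample(c(64L, 128L, 256L, 512L), n, TRUE),
      acquisition_s = 300,
      scatter_correction = sample(c("none", "dual-window"), n, TRUE, prob = c(0.9, 0.1)),
      failed = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.05, 0.95)),
      cc = runif(n, 0.3, 1.1)
    )
    qc <- suppressWarnings(qc_filter(rec))
    expect_identical(sum(qc$tally$n), n)
    expect_identical(
      sum(qc$tally$n[qc$tally$reason != "eligible"]) + nrow(qc$eligible), n
    )
  }
})

test_that("empty input filters to an empty result with a zero tally", {
  qc <- qc_filter(toy_records()[0, ])
  expect_equal(nrow(qc$eligible), 0L)
  expect_true(all(qc$tally$n == 0L))
  expect_equal(nrow(aggregate_table(qc$eligible)), 0L)
})

test_that("aggregation means, SDs and counts are exact on a toy example", {
  rec <- tibble::tibble(
    vendor = "GE", camera = "Infinia", collimator = "ELEGP",
    cc = c(0.74, 0.76)
  )
  agg <- aggregate_table(rec)
  expect_equal(agg$mean_cc, 0.75)
  expect_equal(agg$sd_cc, sd(c(0.74, 0.76)))
  expect_equal(agg$n, 2L)
  expect_identical(agg$collimator_group, "ELEGP")
})

test_that("wide rendering shows a dash for absent camera-group combinations", {
  rec <- tibble::tibble(
    vendor = c("GE", "GE", "Philips"),
    camera = c("Infinia", "Infinia", "BrightView"),
    collimator = c("LEHR", "MEGP", "CHR"),
    cc = c(0.55, 0.88, 0.53)
  )
  wide <- format_cc_table(aggregate_table(rec))
  expect_identical(wide$CHR[wide$camera == "Infinia"], "–")
  expect_identical(wide$LEHR[wide$camera == "Infinia"], "0.55")
  md <- format_cc_table(aggregate_table(rec), format = "markdown")
  expect_true(grepl("^\\|", md[1]))
})

test_that("aggregating a generated database recovers the planted group means", {
  qc <- qc_filter(generate_database(synth_db_spec(), seed = 14))
  agg <- aggregate_table(qc$eligible)
  pooled <- dplyr::group_by(agg, .data$collimator_group) |>
    dplyr::summarise(mean_cc = sum(.data$mean_cc * .data$n) / sum(.data$n))
  truth <- mibgcal:::default_group_cc()
  m <- merge(pooled, truth, by.x = "collimator_group", by.y = "group")
  expect_true(all(abs(m$mean_cc - m$mean) < 0.02))
})
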