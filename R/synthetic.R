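## Synthetic multicenter databases and clinical tables.
##
## No public multicenter phantom database exists, so the pipeline is
## exercised on synthetic records that reproduce the documented composition:
## 1648 records of which 145 carry scatter correction, 79 small matrices,
## 297 minor energy windows (with the per-setting breakdown), 14 minor
## collimators/cameras, 22 failed experiments, 20 planted CC outliers and
## 366 otherwise-eligible 159 keV +/- 7.5% acquisitions, leaving 705
## eligible records whose conversion coefficients follow the published
## per-group distributions.

default_group_cc <- function() {
  tibble(
    group = c("CHR", "LEHR", "LEGP", "ELEGP", "LMEGP", "MEGP", "MELP"),
    mean = c(0.545, 0.545, 0.631, 0.745, 0.823, 0.879, 0.894),
    sd = c(0.0268, 0.0414, 0.0455, 0.0268, 0.0437, 0.0429, 0.0349),
    n = c(21L, 167L, 57L, 149L, 102L, 179L, 29L)
  )
}

default_minor_windows <- function() {
  tibble(
    center_kev = c(
      154, 155, 156, 156, 157, 158, 158, 158, 158, 158,
      159, 159, 159, 159, 159, 160, 160, NA
    ),
    halfwidth_pct = c(
      10, 10, 7.5, 10, 10, 10, 10.5, 12, 7, 7.5,
      10.5, 12, 6.3, 8, 9, 10, 7.5, NA
    ),
    n = c(4L, 4L, 1L, 32L, 28L, 101L, 1L, 2L, 1L, 23L, 3L, 1L, 2L, 1L, 1L, 80L, 8L, 4L)
  )
}

default_minor_collimators <- function() {
  tibble(
    vendor = c(rep("Siemens", 5), "GE", "Toshiba", "Toshiba", "Picker", "Hitachi"),
    camera = c(rep("e.cam/Symbia", 5), "Infinia", "e.cam/Symbia", "e.cam/Symbia", "PRISM", "RC-1500I"),
    collimator = c("123I", "Cardiac", "LELP", "LPHR", "MEDIUM", "HEGP", "Cardio", "MEHR", "LEUHR", "LEGP"),
    n = c(1L, 2L, 1L, 1L, 2L, 1L, 1L, 3L, 1L, 1L)
  )
}

## Camera fleet and the collimator groups each camera is paired with,
## mirroring the published camera-by-collimator table; weights follow the
## published per-camera record counts.
default_cameras <- function() {
  tibble(
    vendor = c(
      "GE", "GE", "GE", "GE", "Philips", "Picker",
      "Siemens", "Siemens", "Toshiba"
    ),
    camera = c(
      "Discovery/Optima", "Infinia", "Millennium MG", "Millennium VG",
      "BrightView", "PRISM", "e.cam/Symbia", "EvoExcel/IntevoExcel",
      "e.cam/Symbia"
    ),
    weight = c(121, 151, 33, 33, 36, 73, 110, 12, 79),
    groups = list(
      c("LEHR", "ELEGP", "MEGP"),
      c("LEHR", "ELEGP", "MEGP"),
      c("LEHR", "LEGP", "MEGP"),
      c("LEHR", "LEGP", "MEGP"),
      c("CHR", "MEGP"),
      c("LEHR", "LEGP", "MEGP"),
      c("LEHR", "LMEGP", "MEGP", "MELP"),
      c("LEHR", "LMEGP", "MELP"),
      c("LEHR", "LMEGP", "MEGP", "MELP")
    )
  )
}

#' Specification of a synthetic multicenter phantom database
#'
#' Defaults reproduce the documented composition of the 1648-record
#' multicenter database: per-stratum exclusion counts, the per-setting
#' minor-energy-window breakdown, the minor-equipment list, the per-group
#' conversion-coefficient distributions and the camera fleet.
#'
#' @param n_scatter,n_small_matrix,n_failed,n_outliers,n_window75,n_eligible
#'   Stratum sizes (defaults 145, 79, 22, 20, 366, 705).
#' @param minor_windows Tibble `center_kev`, `halfwidth_pct`, `n` (297 rows'
#'   worth by default, including 4 missing-window records).
#' @param minor_collimators Tibble `vendor`, `camera`, `collimator`, `n`
#'   (14 records by default).
#' @param group_cc Tibble `group`, `mean`, `sd`, `n` of conversion-coefficient
#'   distributions per collimator group.
#' @param cameras Camera fleet with per-camera sampling weights and
#'   supported collimator groups.
#' @param n_institutions Number of distinct institution labels to sample.
#' @return An object of class `mibg_synth_spec` (a list).
#' @export
synth_db_spec <- function(n_scatter = 145L, n_small_matrix = 79L,
                          minor_windows = default_minor_windows(),
                          minor_collimators = default_minor_collimators(),
                          n_failed = 22L, n_outliers = 20L,
                          n_window75 = 366L, n_eligible = 705L,
                          group_cc = default_group_cc(),
                          cameras = default_cameras(),
                          n_institutions = 600L) {
  if (any(group_cc$sd <= 0)) abort("group CC SDs must be > 0")
  spec <- list(
    n_scatter = n_scatter, n_small_matrix = n_small_matrix,
    minor_windows = minor_windows, minor_collimators = minor_collimators,
    n_failed = n_failed, n_outliers = n_outliers,
    n_window75 = n_window75, n_eligible = n_eligible,
    group_cc = group_cc, cameras = cameras,
    n_institutions = n_institutions
  )
  spec$total <- n_scatter + n_small_matrix + sum(minor_windows$n) +
    sum(minor_collimators$n) + n_failed + n_outliers + n_window75 + n_eligible
  structure(spec, class = "mibg_synth_spec")
}

## Deterministic largest-remainder allocation of n records across weights.
allocate_counts <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## iid truncated-normal draws by inverse-CDF.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Stratified (systematic) truncated-normal sample: one draw per probability
## stratum, shuffled. Sample quantiles track population quantiles to O(1/n),
## so Tukey fences computed from such a sample can never clip its bounded
## support -- a guarantee iid draws do not give at small n.
rnorm_strat <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- (seq_len(n) - runif(n)) / n
  x <- qnorm(plo + u * (phi - plo), mean, sd)
  sample(x)
}

## Draw vendor/camera labels for records of a given collimator group.
sample_cameras_for_group <- function(n, group, cameras) {
  ok <- vapply(cameras$groups, function(g) group %in% g, TRUE)
  if (!any(ok)) ok <- rep(TRUE, nrow(cameras)) # fall back to the full fleet
  idx <- which(ok)
  pick <- idx[sample.int(length(idx), n, replace = TRUE, prob = cameras$weight[idx])]
  tibble(vendor = cameras$vendor[pick], camera = cameras$camera[pick])
}

group_label_variants <- function(group) {
  switch(group,
    LEGP = c("LEGP", "LEAP", "LEGAP"),
    MEGP = c("MEGP", "ME", "MEGAP"),
    group
  )
}

## n eligible-style base records for given groups and CC values.
make_system_records <- function(groups, cc, cameras, halfwidth = 10) {
  n <- length(groups)
  cam <- dplyr::bind_rows(lapply(split(seq_len(n), groups), function(i) {
    g <- groups[i[1]]
    out <- sample_cameras_for_group(length(i), g, cameras)
    out$idx <- i
    out
  }))
  cam <- cam[order(cam$idx), ]
  tibble(
    vendor = cam$vendor,
    camera = cam$camera,
    collimator = unname(vapply(groups, function(g) sample(group_label_variants(g), 1), "")),
    window_center_kev = 159,
    window_halfwidth_pct = halfwidth,
    matrix = sample(c(256L, 512L), n, replace = TRUE, prob = c(0.85, 0.15)),
    acquisition_s = sample(c(60, 120, 180, 300, 600, 900), n,
      replace = TRUE, prob = c(0.08, 0.10, 0.15, 0.45, 0.15, 0.07)
    ),
    scatter_correction = "none",
    failed = FALSE,
    cc = cc
  )
}

#' Generate a synthetic multicenter phantom database
#'
#' Emits exactly the strata requested by the spec. Eligible records (and the
#' otherwise-eligible 159 keV +/- 7.5% stratum) receive conversion
#' coefficients drawn from their collimator group's distribution by
#' stratified sampling of a normal truncated at mean +/- 2 SD, then
#' back-solved to `(hmr_ant, hmr_post) = (1 + 1.6 cc, 1 + 2.5 cc)` so the
#' calibration formula reproduces the planted CC exactly. Planted outliers
#' sit at mean + 7 SD, safely beyond any Tukey fence the clean draws can
#' produce. The published group sizes sum to one less than the eligible
#' count; the remainder is assigned to the largest group.
#'
#' @param spec A [synth_db_spec()].
#' @param seed RNG seed; the same seed yields an identical database.
#' @return A tibble of phantom records (one row per phantom image set) with
#'   a `planted_stratum` column recording each record's generating stratum.
#' @examples
#' db <- generate_database(synth_db_spec(), seed = 7)
#' nrow(db)
#' @export
generate_database <- function(spec = synth_db_spec(), seed = NULL) {
  stopifnot(inherits(spec, "mibg_synth_spec"))
  expected <- spec$n_scatter + spec$n_small_matrix + sum(spec$minor_windows$n) +
    sum(spec$minor_collimators$n) + spec$n_failed + spec$n_outliers +
    spec$n_window75 + spec$n_eligible
  if (expected != spec$total) abort("inconsistent spec: stratum counts do not sum to total")

  with_seed(seed, {
    gcc <- spec$group_cc
    n_extra <- spec$n_eligible - sum(gcc$n)
    if (n_extra < 0) abort("group CC sizes exceed the eligible stratum")
    gcc$n_adj <- gcc$n
    if (n_extra > 0) {
      big <- which.max(gcc$n)
      gcc$n_adj[big] <- gcc$n_adj[big] + n_extra
    }

    draw_group_cc <- function(n_per_group) {
      purrr::pmap(
        list(gcc$group, gcc$mean, gcc$sd, n_per_group),
        function(g, m, s, k) {
          if (k == 0) return(NULL)
          tibble(group = g, cc = rnorm_strat(k, m, s, m - 2 * s, m + 2 * s))
        }
      ) |> dplyr::bind_rows()
    }

    ## eligible stratum
    elig <- draw_group_cc(gcc$n_adj)
    eligible <- make_system_records(elig$group, elig$cc, spec$cameras)
    eligible$planted_stratum <- "eligible"

    ## otherwise-eligible +/- 7.5% stratum
    n75 <- allocate_counts(spec$n_window75, gcc$n)
    e75 <- draw_group_cc(n75)
    win75 <- make_system_records(e75$group, e75$cc, spec$cameras, halfwidth = 7.5)
    win75$planted_stratum <- "window_75"

    ## planted outliers: mean + 7 SD
    out_groups <- sample(gcc$group, spec$n_outliers, replace = TRUE, prob = gcc$n)
    out_cc <- gcc$mean[match(out_groups, gcc$group)] +
      7 * gcc$sd[match(out_groups, gcc$group)]
    outliers <- make_system_records(out_groups, out_cc, spec$cameras)
    outliers$planted_stratum <- "cc_outlier"

    mix_cc <- function(n) {
      g <- sample(gcc$group, n, replace = TRUE, prob = gcc$n)
      rnorm_trunc(n, gcc$mean[match(g, gcc$group)], gcc$sd[match(g, gcc$group)], 0.01, 1.2)
    }

    ## scatter-corrected acquisitions
    scat_g <- sample(gcc$group, spec$n_scatter, replace = TRUE, prob = gcc$n)
    scatter <- make_system_records(scat_g, mix_cc(spec$n_scatter), spec$cameras)
    scatter$scatter_correction <- sample(c("dual-window", "triple-window"),
      spec$n_scatter,
      replace = TRUE, prob = c(0.7, 0.3)
    )
    scatter$planted_stratum <- "scatter_correction"

    ## small matrices
    sm_g <- sample(gcc$group, spec$n_small_matrix, replace = TRUE, prob = gcc$n)
    small <- make_system_records(sm_g, mix_cc(spec$n_small_matrix), spec$cameras)
    small$matrix <- sample(c(64L, 128L), spec$n_small_matrix, replace = TRUE, prob = c(0.3, 0.7))
    small$planted_stratum <- "small_matrix"

    ## minor energy windows, with the per-setting breakdown
    mw <- spec$minor_windows[rep(seq_len(nrow(spec$minor_windows)), spec$minor_windows$n), ]
    n_mw <- nrow(mw)
    mw_g <- sample(gcc$group, n_mw, replace = TRUE, prob = gcc$n)
    minorw <- make_system_records(mw_g, mix_cc(n_mw), spec$cameras)
    minorw$window_center_kev <- mw$center_kev
    minorw$window_halfwidth_pct <- mw$halfwidth_pct
    minorw$planted_stratum <- "minor_energy_window"

    ## minor collimators / cameras
    mc <- spec$minor_collimators[rep(seq_len(nrow(spec$minor_collimators)), spec$minor_collimators$n), ]
    n_mc <- nrow(mc)
    minorc <- tibble(
      vendor = mc$vendor, camera = mc$camera, collimator = mc$collimator,
      window_center_kev = 159, window_halfwidth_pct = 10,
      matrix = 256L,
      acquisition_s = 300,
      scatter_correction = "none", failed = FALSE,
      cc = mix_cc(n_mc),
      planted_stratum = "minor_collimator_or_camera"
    )

    ## failed experiments
    f_g <- sample(gcc$group, spec$n_failed, replace = TRUE, prob = gcc$n)
    failedr <- make_system_records(f_g, mix_cc(spec$n_failed), spec$cameras)
    failedr$failed <- TRUE
    failedr$planted_stratum <- "failed_experiment"

    db <- dplyr::bind_rows(eligible, win75, outliers, scatter, small, minorw, minorc, failedr)
    db$hmr_ant <- 1 + 1.6 * db$cc
    db$hmr_post <- 1 + 2.5 * db$cc
    db$institution <- sprintf("I%04d", sample(spec$n_institutions, nrow(db), replace = TRUE))
    db <- db[sample(nrow(db)), ]
    db$record_id <- seq_len(nrow(db))
    dplyr::relocate(db, "record_id", "institution")
  })
}

#' Sample conversion coefficients for one collimator group
#'
#' Independent pseudo-normal draws from a group's conversion-coefficient
#' distribution, truncated to the physically plausible range (0, 1.2).
#'
#' @param group Group label (recorded on the output).
#' @param n Number of draws (>= 1).
#' @param mean,sd Distribution parameters (`sd` > 0; `sd = 0` returns the
#'   mean exactly).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` conversion coefficients with attribute
#'   `group`.
#' @examples
#' x <- generate_group_samples("MEGP", 179, 0.879, 0.0429, seed = 1)
#' mean(x)
#' @export
generate_group_samples <- function(group, n, mean, sd, seed = NULL) {
  if (!(n >= 1)) abort("n must be >= 1")
  if (sd < 0) abort("sd must be >= 0")
  x <- with_seed(seed, {
    if (sd == 0) rep(mean, n) else rnorm_trunc(n, mean, sd, 0, 1.2)
  })
  structure(x, group = group)
}

#' Generate a synthetic clinical HMR table
#'
#' Two images (early, delayed) per subject. A true medium-energy-scale HMR is
#' drawn per diagnosis stratum and de-standardized through each hospital's
#' conversion coefficient to give the stored uncorrected HMR. With
#' `layout = "reclass"` the generator additionally plants the exact
#' reclassification outcome requested: `n_up_events` heart-failure images and
#' `n_up_nonevents` normal images whose classification moves toward abnormal
#' between the uncorrected (threshold `thr_unc`) and standardized (threshold
#' `thr_std`) readings, with no opposite moves anywhere. Planting an
#' upward move requires at least one hospital with
#' `cc > cc_std * (thr_unc - 1) / (thr_std - 1)`.
#'
#' @param n_hf_subjects,n_normal_subjects Subjects per diagnosis stratum.
#' @param hospital_ccs Named numeric vector of institutional conversion
#'   coefficients (names become hospital ids).
#' @param layout `"reclass"` to plant the exact up/down layout, `"random"`
#'   for unconstrained draws.
#' @param n_up_events,n_up_nonevents Planted upward moves per stratum
#'   (defaults 4 and 1, the documented clinical outcome).
#' @param cc_multicenter Optional named vector of multicenter coefficients
#'   per hospital (defaults to the institutional values).
#' @param thr_unc,thr_std Classification thresholds (defaults 2.17, 2.49).
#' @param seed RNG seed.
#' @return A tibble with one row per image: `subject_id`, `hospital`,
#'   `phase`, `diagnosis`, `hmr`, `cc_i`, `cc_multicenter`.
#' @examples
#' scans <- generate_clinical_set(12, 21, c(A = 0.631, B = 0.840), seed = 1)
#' nrow(scans)
#' @export
generate_clinical_set <- function(n_hf_subjects = 12, n_normal_subjects = 21,
                                  hospital_ccs = c(A = 0.631, B = 0.840),
                                  layout = c("reclass", "random"),
                                  n_up_events = 4L, n_up_nonevents = 1L,
                                  cc_multicenter = NULL,
                                  thr_unc = 2.17, thr_std = 2.49,
                                  seed = NULL) {
  layout <- match.arg(layout)
  if (n_hf_subjects < 0 || n_normal_subjects < 0) abort("subject counts must be >= 0")
  if (n_hf_subjects + n_normal_subjects == 0) {
    return(tibble(
      subject_id = character(0), hospital = character(0), phase = character(0),
      diagnosis = character(0), hmr = numeric(0), cc_i = numeric(0),
      cc_multicenter = numeric(0)
    ))
  }
  if (is.null(names(hospital_ccs))) names(hospital_ccs) <- paste0("H", seq_along(hospital_ccs))
  cc_mc <- cc_multicenter %||% hospital_ccs
  cc_std <- cc_std_reference()

  with_seed(seed, {
    subjects <- tibble(
      subject_id = sprintf("S%03d", seq_len(n_hf_subjects + n_normal_subjects)),
      diagnosis = c(rep("heart_failure", n_hf_subjects), rep("normal", n_normal_subjects)),
      hospital = names(hospital_ccs)[
        (seq_len(n_hf_subjects + n_normal_subjects) - 1L) %% length(hospital_ccs) + 1L
      ]
    )
    scans <- tidyr::crossing(subjects, phase = c("early", "delayed"))
    scans$cc_i <- unname(hospital_ccs[scans$hospital])
    scans$cc_multicenter <- unname(cc_mc[scans$hospital])

    ## de-standardization: uncorrected hmr = cc/cc_std * (H - 1) + 1 for a
    ## true reference-scale HMR H
    destd <- function(H, cc) cc / cc_std * (H - 1) + 1

    draw_true <- function(diagnosis, n) {
      if (diagnosis == "heart_failure") {
        rnorm_trunc(n, 1.85, 0.30, 1.20, 2.80)
      } else {
        rnorm_trunc(n, 2.95, 0.35, 2.10, 4.00)
      }
    }
    scans$hmr <- NA_real_
    for (d in unique(scans$diagnosis)) {
      i <- which(scans$diagnosis == d)
      scans$hmr[i] <- destd(draw_true(d, length(i)), scans$cc_i[i])
    }

    if (layout == "reclass") {
      ## the h-interval that moves toward abnormal under this hospital's cc:
      ## h >= thr_unc (read normal uncorrected) with std(h) < thr_std (read
      ## abnormal standardized); std crosses thr_std at
      ## h* = 1 + (thr_std - 1) cc / cc_std, so the interval is [thr_unc, h*)
      up_window <- function(cc) {
        h_star <- 1 + (thr_std - 1) * cc / cc_std
        if (h_star > thr_unc) c(thr_unc, h_star) else NULL
      }
      ## any value in [lo, hi) moves up; outside [min, max) of the two
      ## thresholds' preimages nothing moves
      change_zone <- function(cc) {
        h_star <- 1 + (thr_std - 1) * cc / cc_std
        sort(c(thr_unc, h_star))
      }
      eps <- 0.015
      ## clear every scan out of its hospital's change zone first
      for (j in seq_len(nrow(scans))) {
        z <- change_zone(scans$cc_i[j])
        if (scans$hmr[j] >= z[1] - eps && scans$hmr[j] < z[2] + eps) {
          scans$hmr[j] <- if (scans$diagnosis[j] == "heart_failure") {
            z[1] - eps - runif(1, 0, 0.3)
          } else {
            z[2] + eps + runif(1, 0, 0.3)
          }
        }
      }
      plant <- function(idx_pool, k, label) {
        ok <- idx_pool[vapply(
          idx_pool,
          function(j) !is.null(up_window(scans$cc_i[j])), TRUE
        )]
        if (length(ok) < k) {
          abort(paste0(
            "cannot plant ", k, " upward ", label, " moves: need hospitals with cc > ",
            sprintf("%.3f", cc_std * (thr_unc - 1) / (thr_std - 1))
          ))
        }
        pick <- ok[seq_len(k)]
        for (j in pick) {
          w <- up_window(scans$cc_i[j])
          scans$hmr[j] <<- runif(1, w[1] + 0.005, w[2] - 0.005)
        }
      }
      if (n_up_events > 0) plant(which(scans$diagnosis == "heart_failure"), n_up_events, "event")
      if (n_up_nonevents > 0) plant(which(scans$diagnosis == "normal"), n_up_nonevents, "nonevent")
    }
    scans[order(scans$subject_id, scans$phase), ]
  })
}
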