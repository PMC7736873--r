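## Multicenter phantom database: record QC, outlier removal, aggregation.

QC_REASONS <- c(
  "scatter_correction", "small_matrix", "minor_energy_window",
  "minor_collimator_or_camera", "failed_experiment", "cc_outlier", "window_75"
)

COLLIMATOR_GROUPS <- c("CHR", "LEHR", "LEGP", "ELEGP", "LMEGP", "MEGP", "MELP")

## Canonical-name table: each recognized collimator name maps to one of the
## 7 groups (LEAP/LEGAP fold into LEGP; ME/MEGAP into MEGP).
collimator_aliases <- function() {
  c(
    CHR = "CHR", LEHR = "LEHR",
    LEGP = "LEGP", LEAP = "LEGP", LEGAP = "LEGP",
    ELEGP = "ELEGP", LMEGP = "LMEGP",
    ME = "MEGP", MEGP = "MEGP", MEGAP = "MEGP",
    MELP = "MELP"
  )
}

## Minor-equipment list: (vendor, collimator-name) pairs excluded from the
## multicenter database; any Hitachi system is minor.
minor_equipment <- function() {
  list(
    SIEMENS = c("123I", "CARDIAC", "LELP", "LPHR", "MEDIUM"),
    GE = c("HEGP"),
    TOSHIBA = c("CARDIO", "MEHR"),
    PICKER = c("LEUHR", "LEULTRAHIGHRESOLUTION")
  )
}

norm_name <- function(x) toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))

#' Classify a collimator name into a multicenter group
#'
#' Maps vendor collimator names onto the seven collimator groups used by the
#' multicenter pipeline (`CHR`, `LEHR`, `LEGP` incl. LEAP/LEGAP, `ELEGP`,
#' `LMEGP`, `MEGP` incl. ME/MEGAP, `MELP`). Names on the minor-equipment
#' list (e.g. Siemens 123I/Cardiac/LELP/LPHR/MEDIUM, GE HEGP, Toshiba
#' Cardio/MEHR, Picker LE ultra-high-resolution, any Hitachi system) map to
#' `"excluded"`; unknown names map to `"excluded"` with a warning.
#'
#' @param name Collimator name(s).
#' @param vendor Vendor name(s), recycled against `name`.
#' @return Character vector: a group label or `"excluded"`.
#' @examples
#' classify_collimator("LEAP", "GE")
#' classify_collimator("MEHR", "Toshiba")
#' @export
classify_collimator <- function(name, vendor) {
  nm <- norm_name(name)
  vd <- toupper(trimws(as.character(vendor)))
  if (length(vd) == 1L) vd <- rep(vd, length(nm))
  if (length(vd) != length(nm)) abort("`vendor` must have length 1 or length(name)")
  aliases <- collimator_aliases()
  minors <- minor_equipment()
  out <- character(length(nm))
  unknown <- character(0)
  for (i in seq_along(nm)) {
    if (identical(vd[i], "HITACHI")) {
      out[i] <- "excluded"
    } else if (nm[i] %in% (minors[[vd[i]]] %||% character(0))) {
      out[i] <- "excluded"
    } else if (nm[i] %in% names(aliases)) {
      out[i] <- unname(aliases[[nm[i]]])
    } else {
      out[i] <- "excluded"
      unknown <- c(unknown, if (nzchar(nm[i])) nm[i] else "<empty>")
    }
  }
  if (length(unknown) > 0) {
    warn(paste0(
      "unrecognized collimator name(s) excluded: ",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  out
}

#' Parse an energy-window description
#'
#' Accepts the common textual dialects `"159 ± 10%"`, `"159keV±10%"`,
#' `"159:10"`, `"158 k ± 7%"` and returns the numeric centre (keV) and
#' half-width (%). Unparseable or missing input yields `NA`.
#'
#' @param x Character vector of window descriptions.
#' @return A tibble with columns `center_kev`, `halfwidth_pct`.
#' @export
parse_energy_window <- function(x) {
  x <- as.character(x)
  s <- gsub("\\s+", "", x)
  s <- gsub("(?i)kev|kv|k", "", s, perl = TRUE)
  s <- gsub("\\+/?-", "±", s)
  m <- regmatches(s, regexec("^([0-9]+\\.?[0-9]*)(?:±|:)([0-9]+\\.?[0-9]*)%?$", s))
  centre <- vapply(m, function(g) if (length(g) == 3L) as.numeric(g[2]) else NA_real_, 0)
  half <- vapply(m, function(g) if (length(g) == 3L) as.numeric(g[3]) else NA_real_, 0)
  tibble(center_kev = centre, halfwidth_pct = half)
}

#' Is an energy window a minor (excluded) setting?
#'
#' Only the two primary settings 159 keV +/- 10% and 159 keV +/- 7.5% are
#' retained by the multicenter pipeline; every other centre/width combination
#' (154--160 keV variants) and missing data count as minor. Centres are
#' matched exactly (158 is not rounded to 159).
#'
#' @param center_kev Window centre(s) in keV, or a character vector of window
#'   descriptions (parsed with [parse_energy_window()]).
#' @param halfwidth_pct Window half-width(s) in percent.
#' @return Logical vector: `TRUE` if the window is minor.
#' @examples
#' is_minor_energy_window(159, 10) # FALSE: primary setting
#' is_minor_energy_window(158, 10) # TRUE
#' is_minor_energy_window(NA, NA) # TRUE: missing
#' @export
is_minor_energy_window <- function(center_kev, halfwidth_pct = NULL) {
  if (is.character(center_kev)) {
    p <- parse_energy_window(center_kev)
    center_kev <- p$center_kev
    halfwidth_pct <- p$halfwidth_pct
  }
  ok <- !is.na(center_kev) & !is.na(halfwidth_pct) &
    center_kev == 159 & (halfwidth_pct == 10 | halfwidth_pct == 7.5)
  !ok
}

#' Flag conversion-coefficient outliers within collimator groups
#'
#' Tukey's rule with interpolated quartiles: within each collimator group, a
#' record is flagged when its CC lies outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Groups with fewer than 4 members yield no
#' flags.
#'
#' @param records A data frame of phantom records.
#' @param cc_col,group_col Column names holding the conversion coefficient
#'   and the collimator group.
#' @return Logical vector, one flag per record.
#' @export
detect_cc_outliers <- function(records, cc_col = "cc", group_col = "collimator_group") {
  cc <- records[[cc_col]]
  grp <- records[[group_col]]
  flags <- rep(FALSE, length(cc))
  for (g in unique(grp)) {
    i <- which(grp == g & !is.na(cc))
    if (length(i) < 4L) next
    q <- quantile(cc[i], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flags[i] <- cc[i] < q[1] - 1.5 * iqr | cc[i] > q[2] + 1.5 * iqr
  }
  flags
}

ensure_record_columns <- function(records) {
  records <- as_tibble(records)
  if (!"cc" %in% names(records) &&
    all(c("hmr_ant", "hmr_post") %in% names(records))) {
    records$cc <- cc_from_hmr(records$hmr_ant, records$hmr_post)
  }
  if (!all(c("window_center_kev", "window_halfwidth_pct") %in% names(records))) {
    if ("energy_window" %in% names(records)) {
      p <- parse_energy_window(records$energy_window)
      records$window_center_kev <- p$center_kev
      records$window_halfwidth_pct <- p$halfwidth_pct
    } else {
      abort("records need `window_center_kev`/`window_halfwidth_pct` or `energy_window`")
    }
  }
  needed <- c("vendor", "collimator", "matrix", "scatter_correction", "failed", "cc")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing columns: ", paste(missing, collapse = ", ")))
  }
  records
}

#' Multicenter database selection filter
#'
#' Applies the database selection criteria in their fixed narrative order:
#' (1) scatter-corrected acquisitions (dual/triple energy window), (2) small
#' matrices (64, 128), (3) minor energy-window settings, (4) minor
#' collimators/cameras, (5) failed phantom experiments, (6) conversion-
#' coefficient outliers by Tukey fences within collimator groups among the
#' survivors, and (7), unless `include_75_window = TRUE`, acquisitions at
#' 159 keV +/- 7.5%. A record is tallied under the first rule it matches,
#' so `eligible + sum(exclusions)` always equals the input size.
#'
#' @param records Tibble of phantom records with columns `vendor`, `camera`,
#'   `collimator`, `matrix`, `scatter_correction` (`"none"`, `"dual-window"`,
#'   `"triple-window"` or logical), `failed`, `hmr_ant`/`hmr_post` (or `cc`),
#'   and `window_center_kev`/`window_halfwidth_pct` (or a textual
#'   `energy_window`).
#' @param include_75_window Keep 159 keV +/- 7.5% acquisitions?
#' @return An object of class `mibg_qc`: a list with `eligible` (tibble of
#'   surviving records, with `collimator_group` attached), `tally` (tibble of
#'   per-reason exclusion counts plus the eligible count) and `records` (the
#'   input with an `exclusion_reason` column, `NA` for eligible rows).
#' @examples
#' db <- generate_database(synth_db_spec(), seed = 1)
#' qc <- qc_filter(db)
#' qc$tally
#' @export
qc_filter <- function(records, include_75_window = FALSE) {
  records <- ensure_record_columns(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    scat <- records$scatter_correction
    scat_flag <- if (is.logical(scat)) {
      !is.na(scat) & scat
    } else {
      !is.na(scat) & !(tolower(as.character(scat)) %in% c("none", ""))
    }
    reason[is.na(reason) & scat_flag] <- "scatter_correction"
    reason[is.na(reason) & records$matrix %in% c(64, 128)] <- "small_matrix"
    minor_win <- is_minor_energy_window(records$window_center_kev, records$window_halfwidth_pct)
    reason[is.na(reason) & minor_win] <- "minor_energy_window"
    group <- classify_collimator(records$collimator, records$vendor)
    reason[is.na(reason) & group == "excluded"] <- "minor_collimator_or_camera"
    failed <- !is.na(records$failed) & as.logical(records$failed)
    reason[is.na(reason) & failed] <- "failed_experiment"

    surv <- which(is.na(reason))
    if (length(surv) > 0) {
      sub <- tibble(cc = records$cc[surv], collimator_group = group[surv])
      out_flags <- detect_cc_outliers(sub)
      reason[surv[out_flags]] <- "cc_outlier"
    }
    if (!include_75_window) {
      reason[is.na(reason) & records$window_halfwidth_pct == 7.5] <- "window_75"
    }
    records$collimator_group <- group
  } else {
    records$collimator_group <- character(0)
  }

  tally_n <- c(
    vapply(QC_REASONS, function(r) sum(reason == r, na.rm = TRUE), 0L),
    sum(is.na(reason))
  )
  tally <- tibble(reason = c(QC_REASONS, "eligible"), n = unname(tally_n))
  records$exclusion_reason <- reason
  eligible <- records[is.na(reason), , drop = FALSE]
  eligible$exclusion_reason <- NULL
  structure(
    list(eligible = eligible, tally = tally, records = records),
    class = "mibg_qc"
  )
}

#' @export
print.mibg_qc <- function(x, ...) {
  cat(sprintf(
    "<mibg_qc> %d records: %d eligible, %d excluded\n",
    nrow(x$records), nrow(x$eligible), nrow(x$records) - nrow(x$eligible)
  ))
  print(x$tally)
  invisible(x)
}

#' Tidy / summarize a QC filter result
#'
#' `tidy()` returns the per-reason exclusion tally; `glance()` a one-row
#' summary with input size and eligible count.
#'
#' @param x A `mibg_qc` object.
#' @param ... Unused.
#' @export
tidy.mibg_qc <- function(x, ...) x$tally

#' @rdname tidy.mibg_qc
#' @export
glance.mibg_qc <- function(x, ...) {
  tibble(
    n_records = nrow(x$records),
    n_eligible = nrow(x$eligible),
    n_excluded = nrow(x$records) - nrow(x$eligible)
  )
}

#' Aggregate conversion coefficients by camera and collimator group
#'
#' Arithmetic mean, SD and n of the conversion coefficient for each
#' (vendor, camera, collimator group) combination present in the records.
#' Combinations with no records are simply absent (rendered as a dash by
#' [format_cc_table()]).
#'
#' @param records Pre-filtered records (e.g. `qc_filter(...)$eligible`) with
#'   columns `vendor`, `camera`, `cc` and `collimator_group` (computed from
#'   `collimator`/`vendor` when absent).
#' @return A tibble of class `mibg_cc_table` with columns `vendor`, `camera`,
#'   `collimator_group`, `mean_cc`, `sd_cc`, `n`.
#' @export
aggregate_table <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble(
      vendor = character(0), camera = character(0),
      collimator_group = character(0),
      mean_cc = numeric(0), sd_cc = numeric(0), n = integer(0)
    )
    class(out) <- c("mibg_cc_table", class(out))
    return(out)
  }
  if (!"collimator_group" %in% names(records)) {
    records$collimator_group <- classify_collimator(records$collimator, records$vendor)
  }
  if (!"cc" %in% names(records)) records$cc <- cc_from_hmr(records$hmr_ant, records$hmr_post)
  out <- records |>
    dplyr::group_by(.data$vendor, .data$camera, .data$collimator_group) |>
    dplyr::summarise(
      mean_cc = mean(.data$cc),
      sd_cc = sd(.data$cc),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$vendor, .data$camera, .data$collimator_group)
  class(out) <- c("mibg_cc_table", class(out))
  out
}

#' Render a camera-by-collimator conversion-coefficient table
#'
#' Pivots an [aggregate_table()] result into the familiar wide display with
#' one row per (vendor, camera), one column per collimator group, mean CC
#' rounded to `digits` decimals and absent combinations shown as an en dash.
#'
#' @param table A `mibg_cc_table`.
#' @param digits Display precision (default 2, matching the conventional
#'   presentation).
#' @param format `"wide"` for a tibble, `"markdown"` for a character vector
#'   of markdown table lines.
#' @return A tibble or character vector, depending on `format`.
#' @export
format_cc_table <- function(table, digits = 2, format = c("wide", "markdown")) {
  format <- match.arg(format)
  groups <- intersect(COLLIMATOR_GROUPS, unique(table$collimator_group))
  wide <- table |>
    dplyr::mutate(display = sprintf(paste0("%.", digits, "f"), .data$mean_cc)) |>
    dplyr::select("vendor", "camera", "collimator_group", "display") |>
    tidyr::pivot_wider(
      names_from = "collimator_group", values_from = "display",
      values_fill = "–"
    ) |>
    dplyr::arrange(.data$vendor, .data$camera)
  for (g in setdiff(groups, names(wide))) wide[[g]] <- "–"
  wide <- wide[, c("vendor", "camera", groups), drop = FALSE]
  if (format == "wide") return(wide)
  header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  rows <- apply(wide, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
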