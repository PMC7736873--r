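## Clinical standardization and net reclassification improvement.

#' Classify an HMR value against a threshold
#'
#' `"abnormal"` when `hmr < threshold` (strict), otherwise `"normal"`;
#' a value exactly at the threshold is classified normal.
#'
#' @param hmr HMR value(s), > 0.
#' @param threshold Classification threshold, > 0.
#' @return Character vector of `"abnormal"` / `"normal"`.
#' @examples
#' classify(c(2.16, 2.17, 3.0), 2.17)
#' @export
classify <- function(hmr, threshold) {
  if (any(!is.finite(hmr)) || any(hmr <= 0) || !(threshold > 0)) {
    abort("`hmr` and `threshold` must be > 0")
  }
  ifelse(hmr < threshold, "abnormal", "normal")
}

#' Build a reclassification table from explicit counts
#'
#' Up/down counts of images moved toward the abnormal / normal class between
#' the uncorrected and standardized classification, split by event status
#' (events = heart failure, nonevents = normal diagnosis).
#'
#' @param up_events,down_events,n_events Counts for the heart-failure
#'   stratum.
#' @param up_nonevents,down_nonevents,n_nonevents Counts for the
#'   normal-diagnosis stratum.
#' @param thr_unc,thr_std Thresholds the counts were derived under (metadata
#'   only).
#' @return A tibble of class `mibg_reclass` with columns `stratum`, `n`,
#'   `up`, `down`.
#' @examples
#' nri(reclass_table(4, 0, 24, 1, 0, 42))
#' @export
reclass_table <- function(up_events, down_events, n_events,
                          up_nonevents, down_nonevents, n_nonevents,
                          thr_unc = 2.17, thr_std = 2.49) {
  counts <- c(
    up_events, down_events, n_events,
    up_nonevents, down_nonevents, n_nonevents
  )
  if (any(counts < 0)) abort("reclassification counts must be >= 0")
  if (up_events + down_events > n_events ||
    up_nonevents + down_nonevents > n_nonevents) {
    abort("up + down cannot exceed n in a stratum")
  }
  out <- tibble(
    stratum = c("events", "nonevents"),
    n = c(n_events, n_nonevents),
    up = c(up_events, up_nonevents),
    down = c(down_events, down_nonevents)
  )
  attr(out, "thresholds") <- c(uncorrected = thr_unc, standardized = thr_std)
  class(out) <- c("mibg_reclass", class(out))
  out
}

#' Reclassification between uncorrected and standardized HMR readings
#'
#' For each scan, compares the uncorrected classification
#' (`classify(hmr, thr_unc)`) with the standardized classification
#' (`classify(standardize_hmr(hmr, cc), thr_std)`) and tallies movements
#' toward abnormal ("up") and toward normal ("down") within the
#' heart-failure (events) and normal (nonevents) strata.
#'
#' @param scans Tibble with columns `hmr`, `diagnosis`
#'   (`"heart_failure"`/`"normal"`) and the conversion-coefficient column
#'   selected by `cc_source` (`cc_i` or `cc_multicenter`).
#' @param thr_unc Threshold for uncorrected HMR (default 2.17).
#' @param thr_std Threshold for standardized HMR (default 2.49).
#' @param cc_source Which coefficient standardizes each scan.
#' @return A `mibg_reclass` table (see [reclass_table()]).
#' @export
reclassification_table <- function(scans, thr_unc = 2.17, thr_std = 2.49,
                                   cc_source = c("institutional", "multicenter")) {
  cc_source <- match.arg(cc_source)
  scans <- as_tibble(scans)
  cc_col <- if (cc_source == "institutional") "cc_i" else "cc_multicenter"
  if (!cc_col %in% names(scans)) abort(paste0("scans need a `", cc_col, "` column"))
  cc <- scans[[cc_col]]
  if (any(is.na(cc))) {
    bad <- which(is.na(cc))[1]
    id <- if ("subject_id" %in% names(scans)) scans$subject_id[bad] else paste("row", bad)
    abort(paste0("missing conversion coefficient for scan ", id))
  }
  before <- classify(scans$hmr, thr_unc)
  after <- classify(standardize_hmr(scans$hmr, cc), thr_std)
  up <- before == "normal" & after == "abnormal"
  down <- before == "abnormal" & after == "normal"
  ev <- scans$diagnosis == "heart_failure"
  reclass_table(
    up_events = sum(up[ev]), down_events = sum(down[ev]), n_events = sum(ev),
    up_nonevents = sum(up[!ev]), down_nonevents = sum(down[!ev]), n_nonevents = sum(!ev),
    thr_unc = thr_unc, thr_std = thr_std
  )
}

#' Net reclassification improvement
#'
#' `NRI = [(up_e - down_e)/n_e - (up_ne - down_ne)/n_ne] x 100`, where "up"
#' is movement toward the abnormal class: upward moves are improvements for
#' events (heart failure) and deteriorations for nonevents. Reported in
#' percent; bounded in `[-200, 200]`.
#'
#' @param table A `mibg_reclass` table.
#' @return NRI in percent.
#' @examples
#' nri(reclass_table(4, 0, 24, 1, 0, 42)) # 14.3%
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "mibg_reclass"))
  ev <- table[table$stratum == "events", ]
  ne <- table[table$stratum == "nonevents", ]
  if (ev$n == 0 || ne$n == 0) abort("both strata must be non-empty to compute NRI")
  ((ev$up - ev$down) / ev$n - (ne$up - ne$down) / ne$n) * 100
}

#' @export
print.mibg_reclass <- function(x, ...) {
  cat("<mibg_reclass>\n")
  print(as_tibble(x))
  if (x$n[1] > 0 && x$n[2] > 0) cat(sprintf("NRI = %.1f%%\n", nri(x)))
  invisible(x)
}

#' Tidy / summarize a reclassification table
#'
#' `tidy()` returns the per-stratum counts with net reclassified fractions;
#' `glance()` a one-row summary with the NRI in percent.
#'
#' @param x A `mibg_reclass` object.
#' @param ... Unused.
#' @export
tidy.mibg_reclass <- function(x, ...) {
  out <- as_tibble(x)
  out$net_fraction <- (out$up - out$down) / out$n
  out
}

#' @rdname tidy.mibg_reclass
#' @export
glance.mibg_reclass <- function(x, ...) {
  tibble(
    nri_pct = nri(x),
    n_events = x$n[x$stratum == "events"],
    n_nonevents = x$n[x$stratum == "nonevents"]
  )
}

#' Per-hospital, per-phase HMR summary before and after standardization
#'
#' Standardizes each scan with the selected coefficient source and returns
#' mean and SD of the uncorrected and corrected HMR per hospital and phase.
#' After standardization, hospitals imaging the same population should agree
#' within noise even when their uncorrected means differ.
#'
#' @param scans Tibble with columns `hospital`, `phase`, `hmr` and the
#'   selected coefficient column (`cc_i` or `cc_multicenter`).
#' @param mode `"institutional"` or `"multicenter"`.
#' @return A tibble with one row per hospital x phase: n, mean/SD of
#'   uncorrected and corrected HMR.
#' @export
hospital_comparison <- function(scans, mode = c("institutional", "multicenter")) {
  mode <- match.arg(mode)
  scans <- as_tibble(scans)
  cc_col <- if (mode == "institutional") "cc_i" else "cc_multicenter"
  if (!cc_col %in% names(scans)) abort(paste0("scans need a `", cc_col, "` column"))
  scans$hmr_corrected <- standardize_hmr(scans$hmr, scans[[cc_col]])
  scans |>
    dplyr::group_by(.data$hospital, .data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_uncorrected = mean(.data$hmr),
      sd_uncorrected = sd(.data$hmr),
      mean_corrected = mean(.data$hmr_corrected),
      sd_corrected = sd(.data$hmr_corrected),
      .groups = "drop"
    )
}
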