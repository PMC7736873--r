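## File interchange: 16-bit binary PGM images with JSON sidecars, and CSV
## tables. PGM + JSON is the canonical fixture format: bit-exact,
## dependency-light, diffable metadata.

write_pgm16 <- function(mat, path, maxval = 65535L) {
  vals <- as.integer(round(mat))
  if (any(vals < 0) || any(vals > maxval)) abort("PGM values must be in [0, maxval]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(mat), nrow(mat), maxval), con, eos = NULL)
  ## row-major pixel order, 16-bit big-endian
  writeBin(as.integer(t(mat)), con, size = 2L, endian = "big")
  invisible(path)
}

read_pgm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!identical(magic, "P5")) abort("not a binary PGM (P5) file")
  tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) abort("truncated PGM header")
    if (grepl("\\s", ch)) next
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L)
      if (length(ch) == 0L || grepl("\\s", ch)) break
      tok <- paste0(tok, ch)
    }
    tokens <- c(tokens, tok)
  }
  dims <- as.integer(tokens)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  size <- if (maxval > 255) 2L else 1L
  px <- readBin(con, "integer", n = w * h, size = size, signed = FALSE, endian = "big")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

provenance_block <- function(seed = NULL, config = NULL) {
  list(
    tool = "mibgcal",
    version = as.character(utils::packageVersion("mibgcal")),
    seed = seed,
    config_hash = rlang::hash(config)
  )
}

#' Write an activity map as 16-bit PGM plus JSON sidecar
#'
#' Pixel values are scaled to the full 16-bit range; the scale factor, view,
#' pixel size, compartment densities and provenance go to
#' `<path without ext>.json`.
#'
#' @param activity A `mibg_activity_map`.
#' @param path Output `.pgm` path.
#' @return `path`, invisibly.
#' @export
write_activity_map <- function(activity, path) {
  stopifnot(inherits(activity, "mibg_activity_map"))
  mx <- max(activity)
  scale <- if (mx > 0) 65535 / mx else 1
  write_pgm16(round(unclass(activity) * scale), path)
  meta <- list(
    kind = "activity_map",
    view = attr(activity, "view"),
    pixel_size_mm = attr(activity, "pixel_size_mm"),
    densities = as.list(attr(activity, "densities")),
    value_scale = scale,
    provenance = provenance_block(config = attr(activity, "densities"))
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an activity map written by [write_activity_map()]
#'
#' @param path `.pgm` path with its JSON sidecar alongside.
#' @return A `mibg_activity_map` (without compartment masks).
#' @export
read_activity_map <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- read_pgm16(path) / meta$value_scale
  structure(
    m,
    pixel_size_mm = meta$pixel_size_mm,
    view = meta$view,
    densities = unlist(meta$densities),
    class = c("mibg_activity_map", class(m))
  )
}

#' Write a count image as 16-bit PGM plus JSON sidecar
#'
#' Counts are stored verbatim (they must fit 16 bits); acquisition settings,
#' collimator, view and provenance go to the JSON sidecar.
#'
#' @param image A `mibg_count_image`.
#' @param path Output `.pgm` path.
#' @return `path`, invisibly.
#' @export
write_count_image <- function(image, path) {
  stopifnot(inherits(image, "mibg_count_image"))
  if (max(image) > 65535) abort("counts exceed the 16-bit PGM range")
  write_pgm16(unclass(image), path)
  st <- attr(image, "settings")
  col <- attr(image, "collimator")
  meta <- list(
    kind = "count_image",
    view = attr(image, "view"),
    pixel_size_mm = attr(image, "pixel_size_mm"),
    settings = if (!is.null(st)) unclass(st),
    collimator = if (!is.null(col)) unclass(col),
    provenance = provenance_block(
      seed = if (!is.null(st)) st$seed,
      config = list(settings = st, collimator = col)
    )
  )
  jsonlite::write_json(meta, sidecar_path(path),
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Read a count image written by [write_count_image()]
#'
#' @param path `.pgm` path; the JSON sidecar is read when present.
#' @return A `mibg_count_image`.
#' @export
read_count_image <- function(path) {
  m <- read_pgm16(path)
  sp <- sidecar_path(path)
  meta <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else list()
  new_count_image(
    m,
    pixel_size_mm = meta$pixel_size_mm %||% NA_real_,
    settings = meta$settings,
    collimator = meta$collimator,
    view = meta$view %||% NA_character_,
    source = path
  )
}

#' Read / write phantom-record and clinical CSV tables
#'
#' Thin CSV adapters with the documented column schemas: phantom records
#' (`institution`, `vendor`, `camera`, `collimator`, `window_center_kev`,
#' `window_halfwidth_pct`, `matrix`, `acquisition_s`, `scatter_correction`,
#' `failed`, `hmr_ant`, `hmr_post`, `cc`) and clinical scans (`subject_id`,
#' `hospital`, `phase`, `diagnosis`, `hmr`, `cc_i`, `cc_multicenter`).
#'
#' @param path CSV path.
#' @param x Tibble to write.
#' @return A tibble (readers) or `path` invisibly (writer).
#' @export
read_records_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_records_csv
#' @export
write_records_csv <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
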