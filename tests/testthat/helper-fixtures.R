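# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_phantom <- function(view, n = 256, ...) {
  extra <- list(...)
  key <- paste("phantom", view, n, rlang::hash(extra))
  fx_cache(key, do.call(build_phantom, c(list(380 / n, view), extra)))
}

# Noise-free ideal-system rendering with a long integration so count
# quantization is negligible.
fx_ideal_image <- function(view, n = 256) {
  fx_cache(paste("ideal", view, n), {
    simulate_planar(
      fx_phantom(view, n), ideal_collimator(),
      acquisition_settings(matrix = n, duration_s = 30000),
      noise = FALSE
    )
  })
}

# Long-integration noise-free settings for deterministic comparisons.
quiet_settings <- function(n = 256, ...) {
  acquisition_settings(matrix = n, duration_s = 30000, ...)
}

# A small but structurally complete record table for filter edge cases.
toy_records <- function(...) {
  base <- tibble::tibble(
    institution = "I1", vendor = "GE", camera = "Infinia",
    collimator = "LEHR", window_center_kev = 159, window_halfwidth_pct = 10,
    matrix = 256L, acquisition_s = 300, scatter_correction = "none",
    failed = FALSE, hmr_ant = 1 + 1.6 * 0.55, hmr_post = 1 + 2.5 * 0.55
  )
  rows <- list(...)
  if (length(rows) == 0) {
    return(base)
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    b <- base
    for (nm in names(r)) b[[nm]] <- r[[nm]]
    b
  }))
}
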