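## Automated phantom ROI placement and HMR quantification.

## Mean over a disc of radius r_px centred at each pixel, computed with
## row-wise prefix sums (exact, no FFT wrap-around). Pixels outside the image
## are excluded from both sum and count.
disc_mean_map <- function(img, r_px) {
  n <- nrow(img); m <- ncol(img)
  pz <- cbind(0, t(apply(img, 1, cumsum)))
  acc <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  cols <- seq_len(m)
  for (dy in -r_px:r_px) {
    hw <- floor(sqrt(r_px^2 - dy^2 + 1e-9))
    rows <- seq_len(n) + dy
    ok <- rows >= 1L & rows <= n
    if (!any(ok)) next
    hi <- pmin(cols + hw, m)
    lo <- pmax(cols - hw - 1L, 0L)
    s <- pz[rows[ok], hi + 1L, drop = FALSE] - pz[rows[ok], lo + 1L, drop = FALSE]
    acc[ok, ] <- acc[ok, ] + s
    cnt[ok, ] <- cnt[ok, ] + rep(hi - lo, each = sum(ok))
  }
  acc / cnt
}

disc_mask <- function(dim, row, col, r_px) {
  dr <- outer(seq_len(dim[1]) - row, rep(1, dim[2]))
  dc <- outer(rep(1, dim[1]), seq_len(dim[2]) - col)
  dr^2 + dc^2 <= r_px^2
}

rect_mask <- function(dim, row0, col0, height, width) {
  m <- matrix(FALSE, dim[1], dim[2])
  rows <- row0:(row0 + height - 1L)
  cols <- col0:(col0 + width - 1L)
  m[rows, cols] <- TRUE
  m
}

#' Construct a heart + mediastinum ROI set
#'
#' A circular heart ROI (centre, radius) and an axis-aligned rectangular
#' mediastinal ROI (top-left, width, height), in 0-based pixel coordinates.
#' Both ROIs must lie fully inside the image, be disjoint, and contain at
#' least 20 pixels each.
#'
#' @param heart_row,heart_col Heart ROI centre (0-based row/column).
#' @param heart_radius_px Heart ROI radius in pixels.
#' @param med_row,med_col Mediastinal ROI top-left corner (0-based).
#' @param med_height,med_width Mediastinal ROI size in pixels.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @param pixel_size_mm Pixel pitch in mm.
#' @return An object of class `mibg_roi_set`.
#' @export
roi_set <- function(heart_row, heart_col, heart_radius_px,
                    med_row, med_col, med_height, med_width,
                    dim, pixel_size_mm = NA_real_) {
  dim <- as.integer(dim)
  r <- heart_radius_px
  if (heart_row - r < 0 || heart_col - r < 0 ||
    heart_row + r > dim[1] - 1L || heart_col + r > dim[2] - 1L) {
    abort("heart ROI extends outside the image")
  }
  if (med_row < 0 || med_col < 0 ||
    med_row + med_height > dim[1] || med_col + med_width > dim[2]) {
    abort("mediastinal ROI extends outside the image")
  }
  hm <- disc_mask(dim, heart_row + 1L, heart_col + 1L, r)
  mm <- rect_mask(dim, med_row + 1L, med_col + 1L, med_height, med_width)
  if (sum(hm) < 20L || sum(mm) < 20L) abort("each ROI must contain >= 20 pixels")
  if (any(hm & mm)) abort("heart and mediastinal ROIs must be disjoint")
  structure(
    list(
      heart = list(row = heart_row, col = heart_col, radius_px = r, n_px = sum(hm)),
      mediastinum = list(
        row = med_row, col = med_col,
        height = med_height, width = med_width, n_px = sum(mm)
      ),
      dim = dim,
      pixel_size_mm = pixel_size_mm
    ),
    class = "mibg_roi_set"
  )
}

roi_set_masks <- function(rois) {
  list(
    heart = disc_mask(rois$dim, rois$heart$row + 1L, rois$heart$col + 1L, rois$heart$radius_px),
    mediastinum = rect_mask(
      rois$dim, rois$mediastinum$row + 1L, rois$mediastinum$col + 1L,
      rois$mediastinum$height, rois$mediastinum$width
    )
  )
}

#' @export
print.mibg_roi_set <- function(x, ...) {
  cat(sprintf(
    "<mibg_roi_set> heart disc (row %d, col %d, r %d px, %d px); mediastinum rect (row %d, col %d, %d x %d px)\n",
    x$heart$row, x$heart$col, x$heart$radius_px, x$heart$n_px,
    x$mediastinum$row, x$mediastinum$col, x$mediastinum$height, x$mediastinum$width
  ))
  invisible(x)
}

#' Automatic ROI placement on a phantom image
#'
#' Detects the phantom body by thresholding at `threshold_frac` (default 10%)
#' of the 99th-percentile count, locates the heart as the highest-mean disc
#' of fixed physical radius (default 25 mm) within the heart-side half of the
#' body (left half of the anterior view, right half of the posterior view;
#' upper body half), and places a fixed-size mediastinal rectangle (default
#' 20 x 60 mm) on the body-midline column band at the detected heart-centre
#' row. Ties in the heart template search are broken by smallest row, then
#' smallest column.
#'
#' @param image A `mibg_count_image` (or plain count matrix with a
#'   `pixel_size_mm` attribute).
#' @param view `"anterior"` or `"posterior"`; decides which body half is
#'   searched for the heart.
#' @param heart_radius_mm Heart ROI radius in mm.
#' @param med_width_mm,med_height_mm Mediastinal ROI size in mm.
#' @param threshold_frac Body-detection threshold as a fraction of the 99th
#'   percentile count.
#' @return A [roi_set()].
#' @export
auto_roi_phantom <- function(image, view,
                             heart_radius_mm = 25,
                             med_width_mm = 20, med_height_mm = 60,
                             threshold_frac = 0.10) {
  check_view(view)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  px <- attr(image, "pixel_size_mm")
  if (is.null(px) || !is.finite(px)) abort("image must carry a `pixel_size_mm` attribute")
  if (length(img) == 0L) abort("empty image")
  n <- nrow(img); m <- ncol(img)

  thr <- threshold_frac * quantile(img, 0.99, names = FALSE)
  if (!(thr > 0) || max(img) == min(img)) {
    abort("no body outline found: image is effectively uniform or empty")
  }
  body <- img >= thr
  rows <- which(rowSums(body) > 0)
  cols <- which(colSums(body) > 0)
  mid_row <- (min(rows) + max(rows)) / 2
  mid_col <- (min(cols) + max(cols)) / 2

  r_px <- max(2L, as.integer(round(heart_radius_mm / px)))
  means <- disc_mean_map(img, r_px)
  cand <- body
  idx_r <- seq_len(n); idx_c <- seq_len(m)
  cand[idx_r <= r_px | idx_r > n - r_px, ] <- FALSE
  cand[, idx_c <= r_px | idx_c > m - r_px] <- FALSE
  cand[idx_r > mid_row, ] <- FALSE
  if (view == "anterior") cand[, idx_c > mid_col] <- FALSE else cand[, idx_c < mid_col] <- FALSE
  if (!any(cand)) abort("no admissible heart ROI position found")
  means[!cand] <- -Inf
  best <- which(means == max(means), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2])[1], , drop = TRUE]

  w_px <- max(2L, as.integer(round(med_width_mm / px)))
  h_px <- max(2L, as.integer(round(med_height_mm / px)))
  med_row0 <- as.integer(round(best[1] - h_px / 2))
  med_col0 <- as.integer(round(mid_col - w_px / 2))
  med_row0 <- min(max(med_row0, 1L), n - h_px + 1L)
  med_col0 <- min(max(med_col0, 1L), m - w_px + 1L)

  roi_set(
    heart_row = best[1] - 1L, heart_col = best[2] - 1L, heart_radius_px = r_px,
    med_row = med_row0 - 1L, med_col = med_col0 - 1L,
    med_height = h_px, med_width = w_px,
    dim = c(n, m), pixel_size_mm = px
  )
}

#' Heart-to-mediastinum ratio of a planar image
#'
#' The HMR is the mean counts per pixel in the heart ROI divided by the mean
#' counts per pixel in the mediastinal ROI (all pixels of each ROI,
#' unweighted). Using means rather than sums makes the ratio independent of
#' ROI pixel count over homogeneous regions, and invariant to any global
#' count rescaling.
#'
#' @param image Count image (matrix-like).
#' @param rois A [roi_set()] valid for the image.
#' @return An object of class `mibg_hmr` with fields `hmr`, `heart_mean`,
#'   `mediastinum_mean` and `roi`.
#' @examples
#' img <- structure(matrix(100L, 64, 64), pixel_size_mm = 5.9)
#' rois <- roi_set(20, 20, 5, 40, 40, 8, 8, dim = c(64, 64))
#' compute_hmr(img, rois)$hmr
#' @export
compute_hmr <- function(image, rois) {
  stopifnot(inherits(rois, "mibg_roi_set"))
  if (!all(dim(image) == rois$dim)) abort("ROI set does not match image dimensions")
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  masks <- roi_set_masks(rois)
  heart_mean <- mean(img[masks$heart])
  med_mean <- mean(img[masks$mediastinum])
  if (!(med_mean > 0)) abort("mediastinal ROI mean is zero; cannot form a ratio")
  structure(
    list(
      hmr = heart_mean / med_mean,
      heart_mean = heart_mean,
      mediastinum_mean = med_mean,
      roi = rois
    ),
    class = "mibg_hmr"
  )
}

#' Automatic HMR measurement on a phantom image
#'
#' Convenience wrapper: [auto_roi_phantom()] followed by [compute_hmr()].
#'
#' @inheritParams auto_roi_phantom
#' @param ... Passed to [auto_roi_phantom()].
#' @return An object of class `mibg_hmr`.
#' @export
measure_hmr <- function(image, view = attr(image, "view"), ...) {
  compute_hmr(image, auto_roi_phantom(image, view, ...))
}

#' @export
print.mibg_hmr <- function(x, ...) {
  cat(sprintf(
    "<mibg_hmr> HMR = %.4f (heart %.2f, mediastinum %.2f counts/px)\n",
    x$hmr, x$heart_mean, x$mediastinum_mean
  ))
  invisible(x)
}

#' @rdname compute_hmr
#' @param x A `mibg_hmr` object.
#' @export
tidy.mibg_hmr <- function(x, ...) {
  tibble(
    hmr = x$hmr,
    heart_mean = x$heart_mean,
    mediastinum_mean = x$mediastinum_mean
  )
}
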