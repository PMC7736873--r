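## Digital calibration phantom.
##
## A flat acrylic calibration phantom (380 x 380 mm active area) presents a
## planar 123I-MIBG-like distribution over heart, mediastinum, liver, lungs
## and thyroid compartments. Its anterior and posterior faces are built to
## present designated heart-to-mediastinum ratios of 2.60 and 3.50. Here each
## view is modelled as a 2D designated-activity map: the anterior/posterior
## difference is carried by the per-view heart density, not by depth-dependent
## attenuation, because the calibration mathematics only consumes the two
## per-view measured HMRs.

PHANTOM_EXTENT_MM <- 380

## Designated heart-to-mediastinum ratios of the calibration phantom.
DESIGNATED_HMR <- c(anterior = 2.60, posterior = 3.50)

## Compartment geometry in physical mm, anterior view. Origin is the top-left
## corner; x runs along columns (column 0 = patient right), y along rows
## (row 0 = superior). Shapes are the module's own simple primitives; only the
## heart/mediastinum designated ratio is normative.
phantom_geometry <- function() {
  list(
    body        = list(type = "ellipse", cx = 190, cy = 190, rx = 165, ry = 175),
    heart       = list(type = "disc",    cx = 135, cy = 140, r = 30),
    mediastinum = list(type = "rect",    x0 = 175, x1 = 205, y0 = 100, y1 = 180),
    thyroid     = list(type = "ellipse", cx = 190, cy = 48,  rx = 20, ry = 15),
    liver       = list(type = "rect",    x0 = 220, x1 = 330, y0 = 235, y1 = 330),
    lung_left   = list(type = "ellipse", cx = 88,  cy = 150, rx = 36, ry = 65),
    lung_right  = list(type = "ellipse", cx = 292, cy = 150, rx = 36, ry = 65)
  )
}

## Reference ROIs used to assert the designated ratio on the rendered grid:
## strictly interior to their compartments so the ratio of ROI means equals
## the density ratio exactly.
phantom_reference_rois <- function() {
  list(
    heart       = list(type = "disc", cx = 135, cy = 140, r = 25),
    mediastinum = list(type = "rect", x0 = 180, x1 = 200, y0 = 110, y1 = 170)
  )
}

shape_mask <- function(shape, x, y) {
  X <- matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE)
  Y <- matrix(y, nrow = length(y), ncol = length(x))
  switch(shape$type,
    ellipse = ((X - shape$cx) / shape$rx)^2 + ((Y - shape$cy) / shape$ry)^2 <= 1,
    disc    = (X - shape$cx)^2 + (Y - shape$cy)^2 <= shape$r^2,
    rect    = X >= shape$x0 & X <= shape$x1 & Y >= shape$y0 & Y <= shape$y1,
    abort(paste0("unknown shape type '", shape$type, "'"))
  )
}

check_view <- function(view) {
  if (!(is.character(view) && length(view) == 1L && view %in% c("anterior", "posterior"))) {
    abort("`view` must be \"anterior\" or \"posterior\"")
  }
  view
}

#' Designated heart-to-mediastinum ratio of the calibration phantom
#'
#' The calibration phantom is constructed to present a heart-to-mediastinum
#' ratio (HMR) of 2.60 on its anterior face and 3.50 on its posterior face.
#' These two constants anchor the whole conversion-coefficient calibration.
#'
#' @param view `"anterior"` or `"posterior"`.
#' @return The designated HMR (2.60 or 3.50).
#' @examples
#' designated_hmr("anterior")
#' designated_hmr("posterior")
#' @export
designated_hmr <- function(view) {
  unname(DESIGNATED_HMR[[check_view(view)]])
}

default_phantom_densities <- function(view) {
  c(
    heart       = designated_hmr(view),
    mediastinum = 1.0,
    liver       = 3.0,
    lungs       = 0.5,
    thyroid     = 2.0,
    background  = 0.45
  )
}

## Build the disjoint compartment masks on an n x n lattice. Priority order
## resolves overlapping primitives (heart wins over lungs, etc.); every mask
## is clipped to the body outline. Posterior masks are the exact left-right
## mirror of the anterior lattice.
phantom_masks <- function(n, pixel_size_mm, view) {
  geom <- phantom_geometry()
  coords <- (seq_len(n) - 0.5) * pixel_size_mm
  body <- shape_mask(geom$body, coords, coords)
  priority <- c("heart", "mediastinum", "thyroid", "liver", "lung_left", "lung_right")
  taken <- matrix(FALSE, n, n)
  masks <- list()
  for (nm in priority) {
    m <- shape_mask(geom[[nm]], coords, coords) & body & !taken
    taken <- taken | m
    masks[[nm]] <- m
  }
  masks$lungs <- masks$lung_left | masks$lung_right
  masks$lung_left <- masks$lung_right <- NULL
  masks$background <- body & !taken
  masks$body <- body
  ref <- phantom_reference_rois()
  masks$ref_heart <- shape_mask(ref$heart, coords, coords)
  masks$ref_mediastinum <- shape_mask(ref$mediastinum, coords, coords)
  if (view == "posterior") masks <- lapply(masks, function(m) m[, rev(seq_len(n)), drop = FALSE])
  masks
}

#' Render the digital calibration phantom as an activity map
#'
#' Renders one view of the digital calibration phantom as a noise-free 2D
#' relative-activity grid. Compartment geometry is identical between views
#' (the posterior view is the left-right mirror of the anterior layout); the
#' per-view heart density is set so that the reference-ROI heart/mediastinum
#' ratio equals the designated HMR for that view (2.60 anterior, 3.50
#' posterior).
#'
#' @param pixel_size_mm Pixel pitch in mm. Must resolve the 380 mm phantom
#'   extent into at least 64 pixels (i.e. `pixel_size_mm <= 5.9375`).
#' @param view `"anterior"` or `"posterior"`.
#' @param densities Optional named numeric vector overriding the per-
#'   compartment relative densities (names among `heart`, `mediastinum`,
#'   `liver`, `lungs`, `thyroid`, `background`). Defaults: mediastinum 1.0,
#'   heart = designated HMR of the view, liver 3.0, lungs 0.5, thyroid 2.0,
#'   background 0.45. All densities must be >= 0.
#' @return A matrix of class `mibg_activity_map` with attributes
#'   `pixel_size_mm`, `view`, `densities` and the compartment `masks`.
#' @examples
#' amap <- build_phantom(380 / 128, "anterior")
#' attr(amap, "view")
#' @export
build_phantom <- function(pixel_size_mm, view, densities = NULL) {
  check_view(view)
  if (!(is.numeric(pixel_size_mm) && length(pixel_size_mm) == 1L && pixel_size_mm > 0)) {
    abort("`pixel_size_mm` must be a positive length in mm")
  }
  n <- as.integer(round(PHANTOM_EXTENT_MM / pixel_size_mm))
  if (n < 64L) {
    abort(sprintf(
      "pixel size %.3f mm is too coarse: 380 mm must span >= 64 pixels (got %d)",
      pixel_size_mm, n
    ))
  }
  dens <- default_phantom_densities(view)
  if (!is.null(densities)) {
    if (is.null(names(densities)) || !all(names(densities) %in% names(dens))) {
      abort("`densities` must be named with compartment names")
    }
    dens[names(densities)] <- densities
  }
  if (any(dens < 0)) abort("compartment densities must be >= 0")

  masks <- phantom_masks(n, pixel_size_mm, view)
  a <- matrix(0, n, n)
  for (nm in c("heart", "mediastinum", "liver", "lungs", "thyroid", "background")) {
    a[masks[[nm]]] <- dens[[nm]]
  }
  structure(
    a,
    pixel_size_mm = pixel_size_mm,
    view = view,
    densities = dens,
    masks = masks,
    class = c("mibg_activity_map", class(a))
  )
}

## Ratio of reference-ROI means on the rendered grid; used by invariants
## and tests rather than trusting the density table.
reference_roi_ratio <- function(activity) {
  masks <- attr(activity, "masks")
  mean(activity[masks$ref_heart]) / mean(activity[masks$ref_mediastinum])
}

#' @export
print.mibg_activity_map <- function(x, ...) {
  cat(sprintf(
    "<mibg_activity_map> %s view, %d x %d px @ %.3f mm, reference ratio %.4f\n",
    attr(x, "view"), nrow(x), ncol(x), attr(x, "pixel_size_mm"),
    reference_roi_ratio(x)
  ))
  invisible(x)
}
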