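## Collimator and acquisition descriptors for the simplified planar simulator.

## 123I photon branching fractions: 159 keV photopeak and the 529 keV
## high-energy line responsible for septal penetration.
BRANCHING_159 <- 0.833
BRANCHING_529 <- 0.0139

## Detector sensitivity calibrated so a 55.5 MBq phantom acquired for 5 min
## yields ~1.0e6 total counts.
DEFAULT_SENSITIVITY <- 1e6 / (55.5 * 300)

#' Parallel-hole collimator specification
#'
#' Describes a parallel-hole collimator by its hole diameter, septal
#' thickness and length, plus the lead attenuation coefficients at the
#' 159 keV photopeak and the 529 keV high-energy line. These five numbers
#' drive both the geometric resolution model and the septal-penetration
#' fraction.
#'
#' @param hole_diameter_mm Hole diameter d in mm (0.5--5).
#' @param septal_thickness_mm Septal thickness t in mm (0.05--2).
#' @param length_mm Collimator length L in mm (10--80).
#' @param name Optional label.
#' @param group Optional collimator group label (e.g. `"LEHR"`, `"MEGP"`).
#' @param mu159_mm,mu529_mm Septal linear attenuation per mm at 159 and
#'   529 keV. Defaults 2.3 and 0.17 (lead).
#' @return An object of class `mibg_collimator`.
#' @examples
#' collimator_spec(1.11, 0.16, 24.05, name = "LEHR-like", group = "LEHR")
#' @export
collimator_spec <- function(hole_diameter_mm, septal_thickness_mm, length_mm,
                            name = NULL, group = NA_character_,
                            mu159_mm = 2.3, mu529_mm = 0.17) {
  d <- hole_diameter_mm; t <- septal_thickness_mm; L <- length_mm
  if (!(is.numeric(d) && length(d) == 1L && d >= 0.5 && d <= 5)) {
    abort("hole diameter must be in [0.5, 5] mm")
  }
  if (!(is.numeric(t) && length(t) == 1L && t >= 0.05 && t <= 2)) {
    abort("septal thickness must be in [0.05, 2] mm")
  }
  if (!(is.numeric(L) && length(L) == 1L && L >= 10 && L <= 80)) {
    abort("collimator length must be in [10, 80] mm")
  }
  if (!(mu159_mm > 0 && mu529_mm > 0)) abort("attenuation coefficients must be > 0")
  structure(
    list(
      name = name %||% sprintf("d%.2f-t%.2f-L%.1f", d, t, L),
      group = group,
      hole_diameter_mm = d,
      septal_thickness_mm = t,
      length_mm = L,
      mu159_mm = mu159_mm,
      mu529_mm = mu529_mm,
      ideal = FALSE
    ),
    class = "mibg_collimator"
  )
}

#' Ideal (aberration-free) imaging system
#'
#' A degenerate collimator with zero geometric blur and zero septal
#' penetration. Useful as the reference system: imaging the digital phantom
#' through it reproduces the designated HMR exactly (up to count rounding).
#'
#' @return An object of class `mibg_collimator` flagged as ideal.
#' @export
ideal_collimator <- function() {
  structure(
    list(
      name = "ideal", group = NA_character_,
      hole_diameter_mm = 0, septal_thickness_mm = Inf, length_mm = Inf,
      mu159_mm = 2.3, mu529_mm = 0.17, ideal = TRUE
    ),
    class = "mibg_collimator"
  )
}

#' Representative collimator presets
#'
#' Plausible hole-diameter / septal-thickness / length triples for the seven
#' collimator groups handled by the multicenter pipeline. The LEHR and MEGP
#' entries follow commonly published design values; the others interpolate
#' between them. These are illustrative systems for simulation, not vendor
#' data.
#'
#' @return A named list of `mibg_collimator` objects.
#' @examples
#' names(collimator_presets())
#' @export
collimator_presets <- function() {
  specs <- list(
    CHR   = c(1.22, 0.20, 27.0),
    LEHR  = c(1.11, 0.16, 24.05),
    LEGP  = c(1.78, 0.30, 32.8),
    ELEGP = c(2.00, 0.50, 35.0),
    LMEGP = c(2.00, 0.90, 40.0),
    MEGP  = c(2.94, 1.14, 48.0),
    MELP  = c(3.40, 1.40, 58.4)
  )
  lapply(setNames(names(specs), names(specs)), function(nm) {
    s <- specs[[nm]]
    collimator_spec(s[1], s[2], s[3], name = nm, group = nm)
  })
}

#' @export
print.mibg_collimator <- function(x, ...) {
  if (isTRUE(x$ideal)) {
    cat("<mibg_collimator> ideal system (no blur, no penetration)\n")
  } else {
    cat(sprintf(
      "<mibg_collimator> %s: d = %.2f mm, t = %.2f mm, L = %.1f mm\n",
      x$name, x$hole_diameter_mm, x$septal_thickness_mm, x$length_mm
    ))
  }
  invisible(x)
}

#' Planar acquisition settings
#'
#' @param window_center_kev Energy-window centre in keV (photopeak 159).
#' @param window_halfwidth_pct Energy-window half-width in percent (e.g. 10
#'   for 159 keV +/- 10%).
#' @param matrix Image matrix size per side; one of 64, 128, 256, 512.
#' @param pixel_size_mm Pixel pitch in mm; defaults to 380 mm / `matrix` so
#'   the phantom fills the field of view.
#' @param duration_s Acquisition duration in seconds.
#' @param distance_mm Collimator-face to phantom-surface distance in mm.
#' @param activity_mbq Total activity in the phantom in MBq.
#' @param seed Optional RNG seed for Poisson noise; the same seed with the
#'   same inputs yields a bit-identical image.
#' @param sensitivity_cps Detected count rate per MBq per second. The default
#'   is calibrated so 55.5 MBq imaged for 5 minutes gives ~1.0e6 counts.
#' @return An object of class `mibg_settings`.
#' @examples
#' acquisition_settings(matrix = 256, duration_s = 300)
#' @export
acquisition_settings <- function(window_center_kev = 159,
                                 window_halfwidth_pct = 10,
                                 matrix = 256,
                                 pixel_size_mm = NULL,
                                 duration_s = 300,
                                 distance_mm = 30,
                                 activity_mbq = 55.5,
                                 seed = NULL,
                                 sensitivity_cps = DEFAULT_SENSITIVITY) {
  if (!matrix %in% c(64L, 128L, 256L, 512L)) abort("matrix must be one of 64, 128, 256, 512")
  if (!(window_halfwidth_pct > 0)) abort("window half-width must be > 0")
  if (!(duration_s > 0)) abort("duration must be > 0")
  if (!(distance_mm >= 0)) abort("distance must be >= 0")
  structure(
    list(
      window_center_kev = window_center_kev,
      window_halfwidth_pct = window_halfwidth_pct,
      matrix = as.integer(matrix),
      pixel_size_mm = pixel_size_mm %||% (PHANTOM_EXTENT_MM / matrix),
      duration_s = duration_s,
      distance_mm = distance_mm,
      activity_mbq = activity_mbq,
      seed = seed,
      sensitivity_cps = sensitivity_cps
    ),
    class = "mibg_settings"
  )
}

#' Geometric resolution of a parallel-hole collimator
#'
#' Standard parallel-hole resolution model: the full width at half maximum of
#' the geometric point-spread function is `d * (L_eff + z) / L_eff`, where
#' `L_eff = L - 2/mu159` is the septal-penetration-corrected effective length
#' (clamped to at least `L/2`) and `z` the source distance. At the collimator
#' face the FWHM equals the hole diameter; it grows linearly with distance.
#'
#' @param collimator A [collimator_spec()] object.
#' @param distance_mm Source-to-collimator distance in mm (>= 0).
#' @return FWHM in mm.
#' @examples
#' geometric_fwhm(collimator_spec(2, 0.3, 40 + 2 / 2.3), 0)
#' @export
geometric_fwhm <- function(collimator, distance_mm) {
  stopifnot(inherits(collimator, "mibg_collimator"))
  if (!(is.numeric(distance_mm) && all(distance_mm >= 0))) abort("distance must be >= 0")
  if (isTRUE(collimator$ideal)) return(rep(0, length(distance_mm)))
  L <- collimator$length_mm
  L_eff <- max(L - 2 / collimator$mu159_mm, L / 2)
  collimator$hole_diameter_mm * (L_eff + distance_mm) / L_eff
}

#' Septal-penetration count fraction
#'
#' Fraction of accepted counts contributed by 529 keV photons that cross the
#' collimator septa. The minimal septal path is `w = L * t / (2 d + t)`; the
#' penetrating branch is weighted by the 529 keV branching fraction (1.39%),
#' attenuated by `exp(-mu529 * w)`, and scaled by a window-acceptance factor
#' `a = half-width% / 7.5` (wider photopeak windows accept more down-scattered
#' high-energy events); the photopeak branch carries the 159 keV branching
#' fraction (83.3%). The fraction decreases with septal thickness and length,
#' and increases with hole diameter and window width.
#'
#' @param collimator A [collimator_spec()] object.
#' @param window_halfwidth_pct Photopeak window half-width in percent
#'   (default 10), or an [acquisition_settings()] object.
#' @return Penetration fraction in `[0, 1]`.
#' @examples
#' lehr <- collimator_spec(1.11, 0.16, 24.05)
#' megp <- collimator_spec(2.94, 1.14, 48)
#' penetration_fraction(lehr) > penetration_fraction(megp)
#' @export
penetration_fraction <- function(collimator, window_halfwidth_pct = 10) {
  stopifnot(inherits(collimator, "mibg_collimator"))
  if (inherits(window_halfwidth_pct, "mibg_settings")) {
    window_halfwidth_pct <- window_halfwidth_pct$window_halfwidth_pct
  }
  if (isTRUE(collimator$ideal)) return(0)
  a <- window_halfwidth_pct / 7.5
  w <- collimator$length_mm * collimator$septal_thickness_mm /
    (2 * collimator$hole_diameter_mm + collimator$septal_thickness_mm)
  pen <- BRANCHING_529 * a * exp(-collimator$mu529_mm * w)
  pen / (pen + BRANCHING_159)
}
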