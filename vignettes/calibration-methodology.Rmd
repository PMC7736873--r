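---
title: "Phantom-based calibration of cardiac 123I-MIBG heart-to-mediastinum ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based calibration of cardiac 123I-MIBG heart-to-mediastinum ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibgcal)
```

## The problem

Cardiac sympathetic innervation is imaged with planar ^123^I-MIBG
scintigraphy and summarized by a single number, the heart-to-mediastinum
ratio (HMR): mean counts per pixel in a cardiac region of interest divided
by mean counts per pixel in an upper-mediastinal region. The HMR carries
prognostic thresholds (e.g. 2.2 on the medium-energy scale), but its value
depends strongly on the acquiring hardware. The 529 keV high-energy line of
^123^I (branching fraction 1.39%, against 83.3% for the 159 keV photopeak)
penetrates the thin septa of low-energy collimators and deposits a diffuse
haze over the image that depresses the measured HMR; collimator hole
geometry adds further variation. The same patient can therefore yield an
HMR of 1.9 on one camera and 2.4 on another.

The remedy implemented here is phantom-based cross-calibration. A flat
calibration phantom presents known, designated HMR values — **2.60** in the
anterior view and **3.50** in the posterior view. Imaging it on a given
system and measuring both views yields the system's **conversion
coefficient**

$$\mathrm{CC} \;=\; \frac{(\mathrm{HMR_{ant}} + \mathrm{HMR_{post}})/2 - 1}
{(2.60 + 3.50)/2 - 1},$$

the fraction of the designated excess ratio the system actually recovers
(the denominator is 2.05). Clinical values are then mapped onto the
medium-energy general-purpose (MEGP) reference scale, whose coefficient is
fixed at $\mathrm{CC_{std}} = 0.88$, by the affine standardization

$$\mathrm{HMR_{std}} \;=\; \frac{\mathrm{CC_{std}}}{\mathrm{CC_i}}
(\mathrm{HMR_i} - 1) + 1 .$$

The map fixes HMR = 1 (no cardiac excess is invariant), preserves patient
ordering, and composes across systems: calibrating A to B and B to the
reference equals calibrating A to the reference directly. We deliberately do
not clamp standardized values below 1; the affine map is the normative
content and pathological inputs should stay visible.

## The digital phantom

`build_phantom()` renders a 380 × 380 mm digital analogue of the acrylic
calibration phantom, one view at a time, as a noise-free relative-activity
map with heart, mediastinum, liver, lung, thyroid and body-background
compartments. Two modelling choices matter:

* **Per-view designated maps, not 3D transport.** The physical phantom
  realizes its anterior/posterior HMR difference through depth-dependent
  attenuation in the acrylic. The calibration mathematics, however, consumes
  only the two per-view measured HMRs, so each view is modelled as an
  independent 2D map whose heart density equals the designated ratio for
  that view (mediastinum fixed at 1.0). The posterior view is the exact
  left-right mirror of the anterior lattice.
* **Free compartment shapes.** Only the heart/mediastinum ratio is
  normative. Shapes are simple primitives (heart: 60 mm disc left of the
  midline; mediastinum: 30 × 80 mm midline rectangle; ellipses and
  rectangles for the rest). Non-normative densities default to liver 3.0,
  lungs 0.5, thyroid 2.0, background 0.45. The background value is chosen
  so the body outline always clears the 10% detection threshold of the
  automatic ROI procedure in both views and for heart densities up to 4.0,
  which keeps the detected body midline — and hence the mediastinal ROI —
  independent of collimator blur.

Rendering at any admissible pixel size (at least 64 pixels across 380 mm)
reproduces the designated reference-ROI ratio exactly, because the reference
ROIs are strictly interior to uniform compartments.

## The planar simulator

`simulate_planar()` forms the expected image as a two-kernel mixture

$$E = S\,[(1-f)\, G_{\mathrm{geo}} \otimes A + f\, G_{\mathrm{pen}} \otimes A],$$

with `A` the activity map and `S` the scaling to the expected total counts
(activity × duration × sensitivity; the sensitivity default makes a
55.5 MBq phantom at 5 min yield 1.0 × 10^6 counts).

* **Geometric blur.** $G_{\mathrm{geo}}$ is Gaussian with FWHM from the
  standard parallel-hole model $d\,(L_\mathrm{eff}+z)/L_\mathrm{eff}$,
  where $L_\mathrm{eff} = L - 2/\mu_{159}$ (clamped to at least $L/2$) and
  $z$ is the camera distance. Defaults $\mu_{159} = 2.3$/mm and
  $\mu_{529} = 0.17$/mm are nominal lead values; both are configurable.
* **Septal penetration.** The accepted-count fraction of penetrating
  529 keV photons is
  $f = b_{529}\,a\,e^{-\mu_{529} w} / (b_{529}\,a\,e^{-\mu_{529} w} + b_{159})$
  with minimal septal path $w = L t / (2d + t)$ and window-acceptance factor
  $a = \text{half-width}\%/7.5$ — the simplest monotone form that makes
  wider photopeak windows admit more down-scattered high-energy events.
  $f$ falls with septal thickness and length, rises with hole diameter and
  window width.
* **Haze width.** $G_{\mathrm{pen}}$ is a fixed broad Gaussian
  (FWHM 150 mm by default, configurable). We use a fixed width rather than
  a multiple of the geometric FWHM because the penetration point spread is
  governed by 529 keV transport through the septa, not by the 159 keV
  geometric resolution; tying it to the geometric FWHM would make the haze
  of a sharp LEHR collimator nearly local, leaving its heart contrast
  intact and inverting the known ordering of conversion coefficients
  between low- and medium-energy collimators. A diffuse haze destroys
  contrast under the cardiac ROI, which is the mechanism by which
  penetration depresses HMR.
* **Edges, totals, noise.** Kernels are renormalized inside the field of
  view and the expected image is rescaled to the exact target total, so no
  counts are lost off-image. With noise on, pixels are independent Poisson
  draws under the settings seed (same seed, same inputs → bit-identical
  image; the ambient RNG stream is left untouched). With noise off the
  expected image is rounded half-to-even to keep count images integral.

This simulator is deliberately not a photon-transport code: energy spectra,
scatter in the phantom body and detector response are out of scope. Its
contract is to reproduce the *trends* that matter for calibration — HMR
falling with hole diameter and rising with septal thickness and length,
window-width and distance behaviour, and linearity of measured versus
designated HMR — not per-pixel agreement with any physical acquisition.

## Automatic ROI placement

`auto_roi_phantom()` re-designs the automated phantom ROI procedure from
first principles (the clinical algorithm it stands in for is proprietary;
only the resulting HMR enters the calibration mathematics). The body is
thresholded at 10% of the 99th-percentile count; the heart is the
highest-mean disc of fixed 25 mm physical radius in the heart-side upper
body half (template search, ties broken to the smallest row then column);
the mediastinal 20 × 60 mm rectangle sits on the body-midline column at the
detected heart-centre row. Centring on the detected midline and heart row —
rather than searching the midline band for an extremum — is deterministic,
translation covariant, and cannot lock onto the thyroid hot spot. All
physical sizes and the threshold fraction are arguments.

HMR uses unweighted per-pixel means, which makes it independent of ROI pixel
count over homogeneous regions and invariant to global count rescaling.

## Numerical choices

* **Count quantization.** Count images are integer by contract. In
  noise-free characterizations (the ideal-system reference measurement, the
  design sweep, linearity fits) the default 10^6 total counts would leave
  mediastinal means near 33 counts/pixel, where coherent rounding of
  uniform regions moves HMR by up to ~1.5%. Those workflows therefore
  integrate longer (`duration_s = 30000`, ~10^8 counts), pushing
  quantization below 10^-3 — a choice of measurement duration, which is
  free in a noise-free simulation. Noisy workflows keep the documented
  10^6-count operating point.
* **Tukey fences.** Outlier removal uses Q1/Q3 by linear interpolation
  (type-7 quantiles) with 1.5 × IQR fences, computed within collimator
  groups; groups under 4 members are never flagged.
* **Exclusion precedence.** A record is tallied under the *first* matching
  rule in the order: scatter correction, small matrix, minor energy window,
  minor equipment, failed experiment, CC outlier, ±7.5% window. The order
  follows the narrative order of the database workflow; a record that is
  both scatter-corrected and small-matrix counts as scatter-corrected.
* **Window parsing.** `159 ± 10%`, `159keV±10%` and `159:10` are accepted;
  centres are matched exactly (158 is never rounded to 159).

## The synthetic database generator

No public multicenter phantom database exists, so `generate_database()`
fabricates one with the documented composition: 1648 records = 145 scatter-
corrected + 79 small-matrix + 297 minor-window (with the full per-setting
breakdown, including 4 missing windows) + 14 minor-equipment + 22 failed +
20 planted outliers + 366 otherwise-eligible ±7.5% acquisitions + 705
eligible. Eligible coefficients follow the published per-group
distributions (e.g. LEHR 0.545 ± 0.0414, n = 167; ME/MEGP/MEGAP
0.879 ± 0.0429, n = 179). Since the published group sizes sum to 704
against 705 eligible records, the generator assigns the one extra record to
the largest group.

Two design points deserve emphasis:

* **Fence-safe sampling.** Eligible coefficients are drawn by *stratified*
  (systematic-quantile) sampling of a normal truncated at mean ± 2 SD.
  With iid draws, sample Tukey fences clip legitimate values in 1–11% of
  small groups, which would break the exact stratum tallies; stratified
  sampling pins sample quartiles to their population values so the fences
  (≈ ±2.6 SD) can never reach the ±2 SD support. Planted outliers sit at
  mean + 7 SD, far beyond any achievable fence. `generate_group_samples()`,
  used for distribution-recovery checks, keeps plain iid draws truncated to
  the physical range (0, 1.2).
* **Exact back-solve.** Each record's anterior/posterior HMRs are
  back-solved as $(1 + 1.6\,\mathrm{CC},\ 1 + 2.5\,\mathrm{CC})$,
  preserving the designated 1.60/2.50 excess proportions, so the
  calibration formula reproduces the planted coefficient to machine
  precision.

`generate_clinical_set()` builds two images (early, delayed) per subject,
drawing a true MEGP-scale HMR per diagnosis stratum (heart failure
1.85 ± 0.30, normal 2.95 ± 0.35, truncated to plausible ranges) and
de-standardizing through each hospital's coefficient. In its default layout
it additionally plants an exact reclassification outcome — 4 of 24
heart-failure images and 1 of 42 normal images moved toward the abnormal
class between the uncorrected (2.17) and standardized (2.49) thresholds,
nothing moved the other way — by placing selected images inside, and all
others outside, the interval of uncorrected values whose classification
changes under that hospital's coefficient. Upward moves require a hospital
coefficient above $0.88 \times 1.17/1.49 \approx 0.691$; the generator
errors if asked to plant moves no hospital can produce.

What the generator does *not* emulate: per-institution correlations, real
vendor market shares beyond the documented camera frequencies, and any
relationship between acquisition settings and coefficient values within a
group. Tests passing on synthetic data therefore validate the pipeline's
bookkeeping and statistics, not camera physics.

## Reclassification and NRI

`classify()` reads values below the threshold as abnormal, with ties
normal. The net reclassification improvement of a table with events
(heart failure) and nonevents (normal) is

$$\mathrm{NRI} = \left[\frac{\mathrm{up_e} - \mathrm{down_e}}{n_e}
- \frac{\mathrm{up_{ne}} - \mathrm{down_{ne}}}{n_{ne}}\right] \times 100,$$

where "up" is movement toward the abnormal class — an improvement for
events and a deterioration for nonevents, the only reading under which the
documented counts (4/24 up, 1/42 up) give 14.3%. The associated p-value is
out of scope; only the point estimate is computed.

## Problem sizes and runtime

The default analyses run at 256 × 256 matrices; the full 5 × 5 × 5 design
sweep (125 noise-free simulations) and the complete test suite finish in
well under a minute on a single core. Acquisition-time behaviour is
established over 30 Poisson replicates per duration.

## Known limitations

* The simulator's penetration fraction is bounded near 2% by the branching
  ratios, far below the physical count fraction low-energy collimators
  admit; consequently simulated conversion coefficients sit near 1 for all
  systems and only their *ordering and trends* are meaningful. Calibrating
  the haze amplitude to reproduce published group coefficients would
  require spectral modelling that is out of scope.
* The phantom ROI procedure assumes a phantom-like layout (single hot disc
  in the heart-side half, midline mediastinum) and is not a clinical ROI
  algorithm.
* The 1459-record extended database variant is not modelled: its printed
  arithmetic cannot be reconciled exactly with the stratum counts.
* Multicenter coefficients for a clinical site are taken as given
  (`cc_multicenter` column); matching a site to a database row is a lookup
  the user performs with `aggregate_table()` output.
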