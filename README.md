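# mibgcal

Phantom-based calibration and standardization of cardiac ^123^I-MIBG
heart-to-mediastinum ratios.

## The problem

Planar ^123^I-MIBG scintigraphy quantifies cardiac sympathetic innervation
through the **heart-to-mediastinum ratio** (HMR): mean counts per pixel in a
cardiac ROI divided by mean counts per pixel in an upper-mediastinal ROI.
The measured HMR, however, depends on the acquiring gamma-camera/collimator
system — the 529 keV line of ^123^I penetrates thin low-energy collimator
septa and its diffuse haze depresses the ratio — so multicenter studies and
threshold-based prognosis need the values put on a common scale.

`mibgcal` implements the full phantom-based cross-calibration workflow for
physicists and imaging-core-lab analysts:

* a **digital calibration phantom** presenting designated HMRs of 2.60
  (anterior) and 3.50 (posterior), and a simplified **planar simulator**
  (parallel-hole geometric blur + septal-penetration haze + Poisson noise)
  reproducing the collimator-design dependence of the measured HMR;
* **automatic ROI placement** and HMR quantification on phantom images;
* the **conversion coefficient** of a system,

  CC = ((HMR_ant + HMR_post)/2 − 1) / ((2.60 + 3.50)/2 − 1),

  and **standardization** of clinical values onto the medium-energy (MEGP)
  reference scale, HMR_std = CC_std/CC_i × (HMR_i − 1) + 1 with
  CC_std = 0.88;
* the **multicenter database pipeline**: record QC (scatter correction,
  matrix, energy window, minor equipment, failed experiments, Tukey-fence
  outliers), and camera-by-collimator aggregation of coefficients;
* **clinical reclassification** analysis between uncorrected (threshold
  2.17) and standardized (threshold 2.49) readings, summarized as net
  reclassification improvement (NRI);
* **synthetic generators** for multicenter databases and clinical tables,
  so every stage is testable without any external data.

## Worked example

```r
library(mibgcal)

# Simulate an anterior phantom acquisition through an LMEGP-like collimator
amap  <- build_phantom(pixel_size_mm = 380/256, view = "anterior")
lmegp <- collimator_presets()$LMEGP
img   <- simulate_planar(amap, lmegp, acquisition_settings(seed = 1))
measure_hmr(img, "anterior")
#> <mibg_hmr> HMR = 2.5837 (heart 76.29, mediastinum 29.53 counts/px)

# Calibrate the system end to end (anterior + posterior, noise-free)
end_to_end_cc(lmegp, acquisition_settings(duration_s = 30000))
#> <mibg_cc> CC = 0.9952 (institutional; HMR ant 2.593, post 3.488)

# Standardize a clinical HMR measured at a site with CC_i = 0.631
standardize_hmr(2.0, cc_i = 0.631)
#> [1] 2.394612
```

The measured HMR (2.58) sits below the designated 2.60 because blur and
septal penetration always degrade contrast; the conversion coefficient says
this simulated system recovers 99.5% of the designated excess ratio. The
standardized clinical value 2.39 is the site's 2.0 re-expressed on the MEGP
reference scale.

The multicenter pipeline on a synthetic 1648-record database:

```r
db <- generate_database(synth_db_spec(), seed = 7)
qc <- qc_filter(db)
glance(qc)
#>   n_records n_eligible n_excluded
#> 1      1648        705        943

format_cc_table(aggregate_table(qc$eligible))[1:3, ]
#>   vendor camera           CHR   LEHR  LEGP  ELEGP LMEGP MEGP  MELP
#> 1 GE     Discovery/Optima –     0.55  –     0.74  –     0.87  –
#> 2 GE     Infinia          –     0.55  –     0.75  –     0.88  –
#> 3 GE     Millennium MG    –     0.52  0.64  –     –     0.91  –

reclassification_table(generate_clinical_set(seed = 7))
#>   stratum       n    up  down
#> 1 events       24     4     0
#> 2 nonevents    42     1     0
#> NRI = 14.3%
```

Of 1648 synthetic records, 705 survive the selection criteria; the
aggregated table shows the recovered mean conversion coefficient per
camera-collimator cell (dash = no records). In the clinical set, 4 of 24
heart-failure images and 1 of 42 normal images move toward the abnormal
class under standardization, giving NRI = 14.3%.

A command-line wrapper is installed as `exec/mibgcal` with subcommands
`simulate`, `hmr`, `cc`, `standardize`, `db filter`, `db aggregate`, `nri`,
`synthdb`, `synthclinical` and `sweep`; images interchange as 16-bit PGM
plus a JSON metadata sidecar.

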