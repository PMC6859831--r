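# octarep

Quantification of en-face optical coherence tomography angiography (OCTA)
slabs and analysis of their test-retest repeatability.

OCTA produces depth-segmented en-face maps of retinal and choroidal blood
flow. Quantitative indices derived from them — choriocapillaris flow-void
area (CC FV), vessel density (VD) and foveal avascular zone (FAZ) area of
the superficial and deep capillary plexuses — are only usable as imaging
biomarkers once their repeatability is known: how much two scans of the same
eye, minutes apart, disagree through noise, fixation drift and processing
alone. `octarep` implements the full study design for that question:

- **Choriocapillaris flow-void pipeline (6 × 6 mm):** reference-square
  contrast standardization; projection-artifact suppression by overlaying
  the Otsu-binarized superficial plexus and mean-matching the shadowed
  intensities; translation registration of the two same-visit scans
  (normalized cross-correlation over integer shifts) with cropping to the
  overlap; flow-deficit threshold *T = A\_p + 1.96 S\_d* from each scan's
  avascular slab (mean and SD of its pixel intensities); total flow-void
  area as the summed area of pixels at or below *T*.
- **Vessel pipeline (3 × 3 mm):** standardization; Otsu global
  binarization (brighter class = vessel); total vessel area (TVA) by pixel
  summation; VD = TVA / total image area; FAZ area from a manually traced
  polygon (shoelace formula) or a seeded 4-connected flood fill after
  morphological closing of the vessel mask.
- **Agreement statistics:** Bland-Altman analysis with the coefficient of
  repeatability CR = 1.96 × SD of the paired differences and limits of
  agreement bias ± CR; ICC(3,1) (two-way mixed-effects, consistency,
  single measurement — the `ST²/(ST² + SE²)` variance-ratio form) with
  exact F-based 95% confidence intervals; the within-subject coefficient of
  variation from duplicate measurements; and correlation screens of
  disagreement against image quality and clinical activity.
- **Synthetic cohorts:** a generator for paired same-visit en-face scans
  with exact ground truth (vessel density, FAZ area, flow-void fraction,
  projection artifacts, inter-scan shift, between-/within-subject variance
  components), so every stage is validated end to end without patient data.

See `vignettes/octa-repeatability-methods.Rmd` for the model, parameter and
design discussion.

## Worked example

Simulate a small choriocapillaris cohort, write it to disk as PNGs plus a
manifest, and run the full workflow:

```r
library(octarep)

cfg <- cohort_config(n_subjects = 6, grid_px = 128, extent_mm = 6,
                     noise_sd = 5, max_shift_px = 6, slab_set = "cc",
                     seed = 2026)
cohort <- generate_cohort(cfg)
dir <- file.path(tempdir(), "demo")
write_cohort(cohort, dir)

out <- run_full(file.path(dir, "manifest.csv"), max_shift_px = 8)
out$report[, c("index", "n", "bias", "cr", "mean", "cr_over_mean",
               "icc", "cv_percent")]
#>   index n    bias   cr mean cr_over_mean  icc cv_percent
#> 1 cc_fv 6 -0.0249 1.04 6.37        0.163 0.93       5.38
cohort$true_icc
#> [1] 0.9615385
```

The report row reads as: across 6 subjects the mean scan-1 − scan-2
difference in flow-void area was −0.025 mm²; 95% of repeat measurements
agree within CR = 1.04 mm², i.e. 16.3% of the average measured area
(6.37 mm²); the estimated ICC of 0.93 is close to the 0.96 implied by the
simulated variance components, and the within-subject CV is 5.4%.

A single pair can also be processed directly:

```r
pair <- cohort$pairs[[1]]
ccfv_pipeline(pair$scan1, pair$scan2)
#> <ccfv_pair_result> offset (2, -6); flow void 7.376 / 7.420 mm2 of 33.776 mm2
```

The registration recovered the simulated inter-scan shift, both scans were
cropped to the same 33.8 mm² overlap, and the two measured areas
correspond to a flow-void fraction of 0.218–0.220 against a simulated
scan-1 truth of 0.225.

A thin command-line front end over the same functions is included at
`inst/cli/octarep.R` (`simulate`, `run-full`, `repeat` subcommands).

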