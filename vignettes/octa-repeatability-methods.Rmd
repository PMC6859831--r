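---
title: "Quantifying en-face OCTA slabs and their test-retest repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying en-face OCTA slabs and their test-retest repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octarep)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) produces depth-segmented
en-face maps of retinal and choroidal blood flow.  Quantitative indices
derived from these maps — choriocapillaris flow-void area (CC FV), vessel
density (VD) and foveal avascular zone area (FAZ) of the superficial and
deep capillary plexuses (SCP, DCP) — are candidate imaging biomarkers, but
their clinical use hinges on test-retest repeatability: how much two scans
of the same eye, taken minutes apart, disagree purely through acquisition
noise, fixation drift and processing.

`octarep` implements both halves of that study design: the image
quantification pipelines themselves, and the agreement statistics used to
summarize intravisit (scan 1 vs scan 2, same visit) and intraoperator (same
image processed twice) repeatability.  Because raw patient scans cannot be
redistributed, the package ships a synthetic en-face cohort generator with
exact ground truth, so every stage is testable end to end.

## Choriocapillaris flow-void pipeline (6 x 6 mm)

For each scan the pipeline uses three device-segmented slabs: the
choriocapillaris (CC), the superficial plexus (SCP) and the avascular outer
retina.  The stages run in a fixed order:

1. **Standardization.** Every slab is contrast-stretched so that the 1st and
   99th intensity percentiles of a central reference square (half the image
   side) map to 0 and 255.  The central square avoids vignetted borders;
   percentile (rather than min–max) anchoring guards against isolated
   extreme pixels.  The map is linear, so relative contrast is preserved;
   a constant slab cannot be standardized and is returned with a warning.
2. **Projection-artifact suppression.** Superficial vessels cast
   decorrelation shadows onto the CC slab that mimic flow deficits.  The SCP
   slab is binarized (Otsu, brighter class = vessel) and used as an overlay:
   CC intensities under the overlay are linearly rescaled so their mean
   equals the mean outside the overlay.  Mean-matching raises the shadowed
   pixels out of the deficit range deterministically without inventing
   texture; genuinely dark (deficit) pixels under vessels stay at the dark
   end of the rescaled distribution.
3. **Registration and cropping.** The two same-visit CC slabs are aligned by
   exhaustive integer-shift search maximizing normalized cross-correlation
   over the overlap (translation only — the subject is not repositioned
   between scans).  Ties prefer the smallest `|dx| + |dy|`, then
   lexicographic order, so duplicate or featureless inputs yield the zero
   offset.  Both CC and avascular slabs are then cropped to the common
   overlap; the analyzed area shrinks accordingly.
4. **Thresholding and measurement.** The flow-deficit threshold is
   `T = mean + 1.96 * SD` of the cropped, standardized avascular slab
   (population SD; at these pixel counts the sample/population distinction
   is far below measurement noise, and fixing one form keeps results
   bit-reproducible).  Each scan uses its own avascular slab, computed after
   cropping, so threshold and measurement see the same field of view.
   Pixels at or below `T` (inclusive) are flow void; total flow-void area is
   the pixel count times `(extent_mm / grid_px)^2` with no minimum-region
   filtering.

## Vessel pipeline (3 x 3 mm)

SCP or DCP slabs are standardized the same way, then binarized with the Otsu
global threshold (256-bin histogram, between-class variance maximized,
lowest threshold on ties; the brighter class is always labelled vessel
internally, independent of display polarity).  Total vessel area (TVA) is
the vessel-pixel count converted to mm²; vessel density is TVA over the
analyzed area.  DCP slabs are deliberately processed without
projection-artifact removal, mirroring standard practice for this index.

The FAZ supports two delineation modes.  The faithful mode is a manually
traced simple polygon whose area is evaluated with the shoelace formula.
The seeded-automatic mode is an automation stand-in: the vessel mask is
morphologically closed with a 2-px disc (bridging 1-px capillary gaps that
would let the fill leak) and the avascular region is flood-filled
(4-connected) from a seed point; the filled pixel count gives the area.

## Agreement statistics

For paired measurements `m1, m2` per subject, differences are taken as
`d = m1 - m2` (the direction is a convention, fixed for sign
reproducibility):

- **Bland-Altman:** bias = mean(d), coefficient of repeatability
  CR = 1.96 × sample SD(d), 95% limits of agreement bias ± CR, and a
  one-sample t-test of d against zero.  CR divided by the grand mean of the
  per-subject averages gives a CV-like percentage.  `cr_from_loa()`
  recovers a CR from published limits as half the interval width, which is
  robust to the bias and limits being rounded independently in print.
- **ICC(3,1):** the two-way mixed-effects, consistency, single-measurement
  form, `(BMS - EMS) / (BMS + EMS)` for two occasions, with the exact
  F-based 95% confidence interval.  The mean squares come from a standard
  two-way ANOVA fit.  In variance-component terms this estimates
  `ST² / (ST² + SE²)` — between-subject over total variance — which is why
  a heterogeneous cohort can show a high ICC even when absolute
  disagreement is large; CR and CV are reported alongside for that reason.
- **CV:** with duplicates, the within-subject variance per subject is
  `(m1 - m2)² / 2`; the within-person SD is the root mean of these and the
  CV is that SD as a percentage of the grand mean (the canonical
  duplicate-measurement form; per-subject CV averaging is not used).
- **Screens:** squared Pearson correlation between absolute differences and
  an image-quality metric, and Pearson r with a clinical-activity
  indicator.

Quality control excludes scans with device signal strength below 7/10, a
motion score above threshold, or a manual floater flag.  The motion score is
a quantitative proxy — the fraction of adjacent row pairs whose correlation
falls below a cutoff — because motion shows up as rows decorrelated from
their neighbours; it is meaningful only on spatially structured slabs, so
the workflow scores the vessel-bearing slab of each scan.

## The synthetic cohort generator

The generator emulates the features the pipelines must cope with, not OCT
physics:

- **Vasculature** is thresholded band-pass (difference-of-Gaussians) spatial
  noise: tortuous, density-controllable (rank thresholding makes the
  achieved vessel fraction exact to a pixel), with a vessel-free FAZ disc
  bounded by a thin capillary ring, as the perifoveal arcade bounds the real
  FAZ.  Band-pass scales track the grid so vessels keep a fixed physical
  width, floored at about 2 px so structures stay resolvable on the coarse
  grids used in tests.
- **Choriocapillaris slabs** draw a known deficit set (rank-thresholded from
  a smoothed latent field, so deficits form patches) at a dark level on a
  bright perfused background.  Projection artifacts darken pixels under the
  SCP mask by 130 intensity levels — deep enough that, without correction,
  shadowed perfused pixels read as flow deficits, which is exactly the
  failure mode the overlay step exists to fix.  The recorded truth predates
  artifact injection.
- **Avascular slabs** are dark with a 2% bright residual-signal fraction.
  This matters: the threshold `T` is transferred from the avascular slab to
  the CC slab after each is standardized against its own reference square,
  so both slabs must span a comparable intensity range for the transfer to
  be meaningful.  A small bright fraction anchors the avascular slab's
  stretch to the same dark-to-bright range as the CC slab and places `T`
  between the deficit and perfused modes.
- **Pairs and cohorts.** Scan 2 images the same scene translated by an
  integer shift with fresh additive Gaussian noise (default SD 5 of 255).
  Subject i's true index is drawn with SD `between_subject_sd` (default
  0.05) around the cohort mean (0.2 for flow-void fraction, 0.3 for vessel
  density); each scan realizes it with error SD `within_subject_sd`
  (default 0.01), implemented through the image construction itself —
  scan 2 re-ranks the same latent field at its own fraction, so the two
  deficit sets are nested and the shared structure stays registerable.  The
  implied ICC, `between² / (between² + within²)`, is recorded as ground
  truth.

What the generator does *not* model: OCT speckle statistics, flow
decorrelation, segmentation errors, rotation or torsion between scans, and
eye-specific anatomy.  Passing recovery tests therefore demonstrates that
the algorithms are implemented correctly and are stable under noise,
translation and projection artifacts — not that they are accurate on
pathological patient scans.

## Numerical choices and edge cases

- Threshold inclusivity is "at or below" (`<=`).
- Otsu ties resolve to the lowest threshold; a constant image is an error
  (no threshold exists).
- Registration default search radius is a tenth of the image side; an
  overlap below 25% of the image at the best shift is an alignment failure.
  The normalized cross-correlation over all shifts is computed with
  zero-padded FFTs (alias-free within the search window) and is verified
  against a direct overlap-subsetting implementation in the tests.
- Area conversion is always `count * (extent_mm / grid_px)^2`; cropping
  reduces the analyzed area, and measured fractions are reported relative
  to the analyzed (cropped) area.
- Degenerate inputs return warnings and sensible no-ops where a no-op is
  well-defined (constant slab in standardization, empty/full overlay mask)
  and errors where no answer exists (constant image in Otsu, zero total
  variance in ICC).

## Problem sizes used in validation

The test-suite and the acceptance script validate ground-truth recovery on
256-px grids (20 full choriocapillaris pipelines across void fractions
0.1–0.4; vessel densities 0.2–0.4), registration on 512-px grids with
shifts up to ±20 px, ICC recovery on simulated cohorts of 500 subjects
(10 replicates per reliability level), and the end-to-end workflow on a
10-subject imaged cohort at 128 px.  These sizes give recovery errors an
order of magnitude below the acceptance bands while keeping a full
validation run in well under a minute.

## Limitations

The registration contract is translation-only; scans with rotation or scale
change need an external alignment step.  The seeded-automatic FAZ mode
requires a closed capillary ring around the seed at the working resolution;
on sparse networks it can leak and overestimate.  The Otsu threshold is
global, so non-uniform illumination biases vessel masks — a known
limitation of the global form.  The published-cohort ICC and CV values
cannot be reproduced without the original patient images; the package
reproduces the procedure and the internally consistent printed summaries,
and validates parameter recovery on synthetic data instead.
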