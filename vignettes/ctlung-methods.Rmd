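---
title: "Semi-automated lung segmentation and radiodensity quantification for mouse micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated lung segmentation and radiodensity quantification for mouse micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlung)
```

## The problem

Experimental lung-injury models in mice (intratracheal bleomycin, Poly-IC,
saline controls) are routinely scored by manual segmentation of micro-CT
slices — slow, subjective work at 5–20 minutes per slice and hundreds of
slices per animal. `ctlung` implements a scriptable, deterministic
alternative: the lung is extracted once per volume by a threshold plus 3D
connected-component analysis with light reader verification, and lung tissue
is then quantified per Hounsfield-unit (HU) radiodensity bin. Injury that
densifies the parenchyma (edema, fibrosis, ground-glass change) appears as a
loss of aerated volume and a right shift of the HU histogram.

## Calibration and the air/tissue mixture model

CT radiodensity is calibrated on two reference materials: air maps to
-1000 HU and water to 0 HU. Under this two-point calibration a voxel's HU
value is read as an affine air/tissue mixture: -1000 HU is pure air, 0 HU
pure water-equivalent tissue, and -500 HU a 50/50 mixture:

```{r}
air_fraction(c(-1000, -500, 0))
```

`air_fraction()` clamps values outside the reference interval (denser than
water, or scanner padding below -1000) before mapping, and warns when it
does. No beam-hardening or nonlinear correction is attempted: the
calibration model is deliberately the two-point linear one.

## HU bin schemes

Three bin schemes partition the radiodensity range:

* **default** — six bins over `[-1000, 0]`:
  `[-1000,-600), [-600,-500), [-500,-400), [-400,-300), [-300,-200), [-200,0]`.
  The aerated bins capture normal parenchyma; `[-200, 0]` is connective
  tissue.
* **mod** — splits the aerated `[-1000, -500]` range into
  `[-1000,-700), [-700,-600), [-600,-500)` for finer discrimination of
  air-dominated tissue (large-airway lumen vs parenchyma), eight bins total.
* **range** — uniform bins of user-chosen width between a user-chosen
  minimum and maximum; the final bin is truncated when the width does not
  divide the span.

The printed forms of such bin lists share boundary values ("-600 to -500"
followed by "-500 to -400"), which leaves boundary ownership ambiguous. The
package resolves this with half-open `[lo, hi)` intervals, the last bin
closed at its top, so every voxel lands in exactly one bin. Voxels outside
the scheme's range are assigned a dedicated `OUT_OF_RANGE` category and
reported as their own row in measurement tables rather than dropped — this
makes conservation checkable: per-bin counts plus out-of-range always sum to
the mask's voxel count, and fractions sum to 1.

## The segmentation pipeline

`segment_lung()` composes five deterministic stages:

1. **Threshold.** Voxels with HU in the closed interval `[-32768, -200]`
   (both defaults adjustable) form the rough mask. The lower bound is the
   int16 minimum, so deep-air and sentinel padding values count as air
   rather than missing data.
2. **3D connected components.** The rough mask is labeled under face (6)
   adjacency by default; 26-adjacency is available by flag. Face adjacency
   is the conservative choice: it prevents diagonal leakage between lung and
   bowel gas. Components are relabeled by descending size with a
   deterministic scan-order tie-break, so labels are reproducible.
3. **Component selection.** The reader's verification step, made
   non-interactive: pass an explicit label, a seed voxel inside the lung, or
   let the automatic mode pick the largest component that does not touch the
   volume boundary on 4 or more of its 6 faces (the exterior-air component
   wraps the animal and touches all of them). Automatic selection is an
   extension; seed/label modes reproduce the interactive verification
   exactly.
4. **Morphological refinement.** Erosion (6-neighborhood, 2 iterations),
   then slice-wise 2D hole filling, then dilation (1 iteration). Erosion
   smooths the boundary and severs thin bridges (trachea/esophagus, gas
   tracks); filling closes enclosed low-density gaps; dilation re-includes
   the pleural rim of connective tissue. The erode-fill-dilate *order* is a
   design choice: eroding first severs bridges before filling can cement
   them, and dilating last restores the pleural margin.
5. **Base crop.** The reader identifies the base (inferior, diaphragm-side)
   slice; all slices below it are zeroed and analysis proceeds base-to-apex,
   excluding sub-diaphragm structures such as bowel gas. `full_stack` keeps
   everything above the base (up to the sinus cavity), `to_apex` stops at
   the last occupied slice.

Given identical inputs and parameters the pipeline is bitwise reproducible —
there is no randomness anywhere in segmentation or measurement.

### Why erode 2 / dilate 1

The refinement radii are genuinely free parameters; they were fixed once by
calibration against the package's own phantom (below), where the true lung
boundary is known exactly. With partial-volume blurring, the -200 HU
iso-surface of the threshold mask sits roughly one voxel *outside* the true
parenchyma boundary (the threshold is crossed about 80% of the way from
parenchyma mean to soft-tissue mean). A symmetric erode/dilate pair would
preserve that outward bias; eroding one voxel more than the dilation
restores it. On the default phantom, (erode 2, dilate 1) recovers the true
volume to within ~3% with Dice ≈ 0.99, whereas e.g. (1, 2) overestimates
volume by ~20%. Both radii remain adjustable per call and are echoed into
the provenance sidecar.

### Slice indexing

Slice indices are 1-based throughout (slice 1 = the inferior end of the
stack), consistent with R's array indexing; `base_slice = 1` therefore means
"keep the whole stack".

## Quantification and the semi-manual workflow

`measure_bins()` counts masked voxels per bin and converts to volume
(count × spacing product, mm³); `measure_slice_roi()` does the same for a 2D
region of interest on one slice, in mm². Per-slice tables report both voxel
count and mm², so either convention of "area" is available downstream.
Fractions are always relative to the full masked voxel count (including
out-of-range), which keeps the conservation identity exact; totals over
in-range bins are reported in a `TOTAL` row and by `total_tissue_volume()`.

The semi-manual workflow is supported by `slice_roi()` /
`roi_from_polygon()` (even-odd rasterization) and `augment_roi()`, which
re-applies a manual ROI at offset slices. The default offsets are
`c(-5, +5)` — each manual slice contributes two additional measured slices.
(An alternative reading of the augmentation step would measure all five
slices above and below; the offsets argument accepts any list, so
`-5:5` reproduces that variant.)

## Agreement statistics

`bland_altman()` implements mean bias and 95% limits of agreement
(bias ± 1.96 × sample SD of the pairwise differences — the standard
Bland-Altman limits; the limits are sometimes loosely called a confidence
interval, but they bound individual differences, not the bias).
`regression_agreement()` fits ordinary least squares of the second series on
the first and reports slope, intercept and Pearson's r. `analyst_deviance()`
summarizes per-slice deviations of each reader from a reference — by default
the across-reader mean, optionally a designated expert.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a synthetic mouse thorax with exact ground
truth, so every stage of the pipeline can be validated without scanner
data. Default grid 128 × 128 × 192 at 0.107 mm isotropic — a quarter-scale
analog of a 512 × 512 × 768 reconstruction at the same spacing, chosen so
the full pipeline runs in seconds on a desktop. Geometry: an ellipsoidal
body with a dense chest-wall shell, two ellipsoidal lung lobes joined by a
carina/main-bronchi airway bridge (without the bridge the "lung" would be
two disconnected components and no single component could represent it), an
embedded cylindrical airway per lobe, a spherical heart notch carved between
the lobes, and a sub-diaphragm gas blob connected to the lung base by a thin
airway tube — present specifically so the base crop has something real to
remove.

Tissue classes (HU mean, SD): exterior air (-1000, 10), lung parenchyma
(-650, 120, clipped to [-1000, -300]), airway lumen (-950, 20),
heart/connective (-100, 60), chest wall/bone (+300, 150). Voxels receive
independent Gaussian noise and the volume is then blurred with a Gaussian of
0.7 voxels to emulate partial-volume averaging; 0.7 voxels keeps the
blurred noise realistic while producing the characteristic HU spillover
across neighboring bins at tissue interfaces. The ground-truth mask is the
exact pre-noise, pre-blur voxel set of parenchyma plus intra-lung airway.
The **fibrotic** preset emulates bleomycin injury: parenchyma mean shifted
to -450 HU (clip [-1000, -250]) and lung axes shrunk 15% — reproducing the
qualitative signature of reduced lung volume with a right-shifted HU
histogram.

What the phantom does *not* emulate: anatomically realistic airway trees and
lobar fissures, cardiac/respiratory motion, reconstruction artifacts
(streaks, rings, beam hardening), and the biological variability of real
cohorts. Passing the phantom tests therefore demonstrates that the
*algorithmic* chain is correct and internally consistent — not that the
specific refinement radii are optimal for any particular scanner or injury
model; those should be verified per protocol against a few manually read
volumes, which is exactly what the agreement module is for.

`simulate_manual_roi()` perturbs a truth slice with a random in-plane
morphological jitter (erode/dilate by a radius drawn uniformly from
`-noise..+noise`), a deliberately simple reader-variability model: it moves
the contour by whole-pixel rims, which matches how manual wand selections
differ at boundaries, but does not simulate gross errors such as including
the pericardium.

## Numerical and degenerate-input choices

* Volumes are held as double-precision HU in memory; Analyze 7.5 I/O stores
  float32 (exact round-trip), TIFF and DICOM store 16-bit integers (HU
  rounded). TIFF carries no spacing, so spacing must be supplied (default
  0.107 mm isotropic, with a warning).
* DICOM `RescaleSlope`/`RescaleIntercept` are always applied on read;
  inconsistent slice spacing beyond 1% is a geometry error.
* Empty masks: labeling an empty mask yields zero components; refinement
  reports which stage emptied a mask; measurement of an empty ROI returns
  all-zero rows with zero fractions.
* Hole filling is slice-wise 2D, not 3D: a 3D fill cannot close cavities
  open at the stack ends, and 2D matches how a reader validates slices.
* Component-size ties in automatic selection go to the lowest label, which
  by the scan-order relabeling rule is itself deterministic.

## Problem sizes used in the validation suite

The shipped tests validate the labeler against a brute-force flood-fill
oracle on fifty random 8 × 8 × 8 grids for both connectivities, run the full
pipeline on the default 128 × 128 × 192 phantom (segmentation, conservation,
volume recovery within 5%, Dice ≥ 0.9, fibrotic shift direction), and run
the reader-agreement analog with six simulated readers on twelve slices.
The Bland-Altman coverage check uses 2000 seed-fixed Monte-Carlo pairs.
These sizes were chosen so the whole suite completes in well under a minute
while still exercising every code path at realistic occupancy.

## Known limitations

* No airway-tree extraction, left/right splitting, or lobe segmentation.
* The automatic component selector assumes the animal is fully inside the
  field of view (exterior air touches most faces); cropped acquisitions
  should use seed selection.
* DICOM support covers uncompressed, explicit-VR little-endian single-frame
  CT series — the common export case — not compressed transfer syntaxes.
* Agreement statistics treat series as paired and exchangeable across
  slices; no within-animal correlation structure is modeled.
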