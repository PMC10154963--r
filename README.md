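# ctlung

Semi-automated lung segmentation and radiodensity quantification for mouse
micro-CT, as an R package with a command-line interface.

Preclinical lung-injury studies (bleomycin fibrosis, Poly-IC, vehicle
controls) are commonly scored by manually outlining the lung on CT slices —
minutes per slice, hundreds of slices per animal, and reader-dependent.
`ctlung` replaces that with a deterministic pipeline a reader only has to
verify: threshold the calibrated Hounsfield-unit (HU) volume, label 3D
connected components, pick the lung component (explicitly, by seed voxel, or
automatically), refine the mask morphologically (erode, fill holes per
slice, dilate to re-include the pleural rim), crop below the identified
base-of-lung slice, and measure lung tissue per HU bin.

## The model in brief

With a two-point air/water calibration (air = −1000 HU, water = 0 HU), HU is
an affine air/tissue mixture scale: a voxel at −500 HU is a 50/50
air-to-tissue mixture. Lung tissue state is summarized by partitioning the
masked voxels into HU bins — by default

```
[−1000,−600) [−600,−500) [−500,−400) [−400,−300) [−300,−200) [−200,0]
```

and reporting per-bin voxel count, volume (count × voxel volume, mm³) and
fraction of total. Injury that densifies the parenchyma shows up as a loss
of total aerated volume and a right shift of this per-bin profile.
Manual-vs-automated (or reader-vs-reader) agreement is quantified with
Bland-Altman bias and 95% limits of agreement (bias ± 1.96 SD of the
pairwise differences) plus ordinary least-squares slope/intercept and
Pearson's r.

A built-in synthetic thorax phantom (ellipsoidal body and chest wall,
two-lobed lung with airways, heart notch, sub-diaphragm decoy gas blob)
provides exact ground truth, so the whole pipeline is validated end-to-end
without scanner data.

## Worked example

```r
library(ctlung)

ph   <- generate_phantom(phantom_spec("default", seed = 42))
mask <- segment_lung(ph$volume, base_slice = ph$base_slice)
mask
#> lung_mask: 171457 voxels in 128 x 128 x 192 grid
#>   volume: 210.0422 mm^3; base slice: 56 ; label: 2

tab <- measure_bins(ph$volume, mask, hu_bin_scheme("default"),
                    volume_id = "phantom42")
tab
#>   volume_id slice    bin_label voxel_count measure_mm  fraction
#> 1 phantom42   ALL [-1000,-600)      146107   178.9874 0.8521495
#> 2 phantom42   ALL  [-600,-500)       20790    25.4686 0.1212549
#> 3 phantom42   ALL  [-500,-400)        4492     5.5029 0.0261990
#> 4 phantom42   ALL  [-400,-300)          68     0.0833 0.0003966
#> 5 phantom42   ALL  [-300,-200)           0     0.0000 0.0000000
#> 6 phantom42   ALL     [-200,0]           0     0.0000 0.0000000
#> 7 phantom42   ALL OUT_OF_RANGE           0     0.0000 0.0000000
#> 8 phantom42   ALL        TOTAL      171457   210.0422 1.0000000

total_tissue_volume(tab)   # mm^3
#> [1] 210.0422
ph$true_volume_mm3         # ground truth: recovered within ~3%
#> [1] 215.882
```

The table reads: 171,457 voxels of segmented lung, 210.04 mm³ of tissue
volume, 85.2% of it in the most aerated bin `[-1000,-600)` — a healthy,
air-filled lung. Running the same pipeline on
`phantom_spec("fibrotic")` (denser, shrunken parenchyma) yields a smaller
total and a per-bin profile shifted toward the denser bins.

The same workflow runs from the shell:

```sh
Rscript inst/cli/ctlung.R phantom  --preset default --seed 42 \
    --out-vol vol.tif --out-truth truth.nii.gz
Rscript inst/cli/ctlung.R run-auto --input vol.tif --spacing 0.107 \
    --base-slice 56 --out-dir out/
```

`run-auto` writes the mask (NIfTI), the measurement CSV, and a JSON
provenance sidecar echoing every resolved parameter and the input checksum;
batch directories are processed volume-by-volume, and one corrupt volume
does not abort the rest.

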