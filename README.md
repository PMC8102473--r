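# mcvbmd

Fully automatic segmentation of the (second) metacarpal bone in calibrated
HR-pQCT volumes and measurement of its volumetric bone mineral density
(vBMD), for researchers who need the expert's slice-by-slice contouring
replaced by a reproducible pipeline.

Arthritis studies quantify hand bone loss with HR-pQCT: 82 um isotropic
voxels, 200–320 slices per scan, densities calibrated to
mg hydroxyapatite/cm^3. The standard workflow requires a trained operator to
contour the bone semi-automatically — 15–30 minutes per scan, with
inter-operator variability. This package implements the automatic
replacement end to end:

* **Segmentation**: a 2D U-Net (five-stage residual encoder, channels
  64–512, standard U-Net decoder) applied slice-wise, or a shallow 3D U-Net
  (channels 2–32, LeakyReLU, first-stage dropout) applied per volume, both
  trained with the soft Dice loss
  `L = 1 − (2|X·Y| + s)/(|X| + |Y| + s)` using Adam. The convolution
  primitives and the reverse-mode training engine are part of the package —
  no deep-learning framework is required.
* **Quantification**: D100, the mean calibrated density over the segmented
  bone, `D100 = (Σ_mask density)/n_voxels`, plus per-slice cross-sectional
  areas and bone volume.
* **Method agreement**: Pearson/Spearman correlation, ICC(2,1), and
  Bland–Altman limits of agreement between manual and automatic
  measurements; Dice/Jaccard/accuracy/AUROC against expert masks
  (with the identity `IoU = DSC/(2 − DSC)` property-tested).
* **Synthetic phantoms**: clinical scans cannot be redistributed, so a
  generator produces calibrated tubular-bone phantoms (cortical shell,
  trabecular interior, erosions, distractor bones, laterality, noise) with
  exact ground-truth masks and contour annotations, making every stage
  testable offline.

## Worked example

A desk-scale end-to-end run — simulate a cohort, train a width-reduced 2D
network, segment, quantify, and compare manual vs automatic D100:

```r
library(mcvbmd)

cfg <- pipeline_config(out_dir = "demo_run", seed = 11)
res <- run_pipeline(cfg)

res$vbmd
#> # A tibble: 8 × 5
#>   case_id manual_d100 automatic_d100 manual_area automatic_area
#>   <chr>         <dbl>          <dbl>       <dbl>          <dbl>
#> 1 case001        409.           406.        6.60           6.58
#> 2 case002        467.           464.        5.10           5.09
#> 3 case003        427.           424.        5.75           5.74
#> # ... 5 more rows

res$agreement
#> <agreement_report> n = 8 pairs
#>   Pearson r 0.9999 (p 9.32e-13), Spearman rho 0.9762 (p 0.000397)
#>   ICC(2,1) 0.9910
#>   Bland-Altman: mean diff -3.033, LoA [-3.597, -2.469]
```

The manual column is computed from the ground-truth expert-style
annotation, the automatic column from the network's post-processed mask;
D100 is in mg HA/cm^3, areas in mm^2. The near-unit correlations say the
automatic pipeline ranks and scales patients like the manual one; the small
negative Bland–Altman mean difference quantifies the automatic pipeline's
slight density underestimation from its marginally tighter masks.
`autoplot(res$agreement)` draws the Bland–Altman plot.

Individual stages are ordinary functions: `generate_phantom()`,
`generate_cohort()`, `preprocess_case()`, `build_unet2d()` /
`build_unet3d()`, `train_model()`, `predict_volume()`,
`postprocess_prediction()`, `compute_vbmd()`, `agreement_stats()`. Volumes
travel as NIfTI/MetaImage with JSON sidecars, contours as documented JSON
(`write_contours()` / `read_contours()`); `exec/mcvbmd` wraps the common
operations for shell use. See the vignette in `vignettes/` for the models,
conventions, and design rationale.

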