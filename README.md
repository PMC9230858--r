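# riblabel

Automatic sequence labeling of the twelve bilateral rib pairs on axial
chest CT, for radiology and medical-image-analysis workflows where
anatomical locations are referenced by rib number and counting ribs by
hand at every reading is the bottleneck.

The package implements the complete pipeline:

* **Ribs-only mask** by intensity-based image processing (IIP):
  window/level display mapping (400/40 HU), binarization at gray level
  140, detection of the vertebral column by template matching with the
  sum of absolute differences

  SAD(u, v) = Σ<sub>(u,v)∈I</sub> |I₁[u, v] − I₂[u, v]|,

  zero padding of the vertebral and facing sternum regions, morphological
  removal of the scanner bed and noise, and exclusion of non-rib bones by
  requiring vertebral contact at each region-grown object's first slice
  of appearance. Alternatively, a binary mask from any external segmenter
  (e.g. a U-net) is ingested directly; a small trainable U-net is
  included.
* **Sequence labeling** by 3D region growing over the six-connected
  neighbourhood: 24 clusters on a full complement, ordered by first
  appearance from the top slice, sided about the vertebral midline,
  paired into rib pairs 1–12, with display annotations on the left ribs.
* **Evaluation**: voxelwise Dice / precision / recall / specificity /
  accuracy, per-case success judgement with a three-class error taxonomy
  (overlapped pair, missed rib, non-rib labeled), and cohort success
  rates with 95% confidence intervals.
* **Synthetic thorax phantom** with voxel-level ground truth (including
  missing-12th-rib and fused-pair variants), so the entire system runs
  and is tested without any external data.

See `vignettes/rib-sequence-labeling.Rmd` for the methods account.

## Worked example

```r
library(riblabel)

# a compact synthetic thorax: 12 rib pairs, vertebra, sternum, bed, clavicle
ph   <- generate_phantom(phantom_spec(ny = 160L, nx = 160L, nz = 56L))
ts   <- generate_template_set(ph)          # 15 vertebra template patches
win  <- apply_window(ph$volume)            # 400/40 HU window
mask <- build_iip_mask(win, ts)            # ribs-only mask
mask
#> <rib_mask> 160 x 160 x 56, 16764 foreground voxels, 56 slice detections

res <- label_sequence(mask, case_id = "demo")
res$report
#> <rib_label_report> case demo: 12 rib pairs, 0 unpaired cluster(s)
head(res$report$annotations, 3)            # left-rib display annotations
#>   ordinal  z   y   x
#> 1       1  5 105 127
#> 2       2  9 105 127
#> 3       3 13 105 127

case_success(res$labels, res$report, ph)   # judge against ground truth
#> <case_result> case demo: SUCCESS

success_rate(46, 50)                       # cohort arithmetic
#> <cohort_result> 46/50 cases, success rate 92.0% (95% CI 84.5-99.5)
```

The label volume codes left rib *i* as *i* and right rib *i* as *12 + i*;
`write_label_volume()`, `write_report()` and `write_overlays()` emit
NIfTI, JSON and annotated per-slice PNGs.

A command-line interface wraps the same functions
(`inst/scripts/riblabel`): subcommands `phantom`, `label`
(`--method iip|mask`), `eval` and `metrics`.

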