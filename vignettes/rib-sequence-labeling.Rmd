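---
title: "Automatic rib sequence labeling on axial chest CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic rib sequence labeling on axial chest CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiologists reading chest CT refer to anatomical locations by rib number,
which means counting the twelve bilateral rib pairs on the axial stack at
every reading. `riblabel` automates this: given an axial CT volume it
produces a ribs-only binary mask, objectifies each rib with
three-dimensional region growing, and assigns ordinal labels 1–12 to every
bilateral pair, with display annotations on the left-side ribs.

Two routes produce the mask:

* **IIP (intensity-based image processing)** — a deterministic pipeline of
  thresholding, template matching, zero padding and morphological cleanup,
  requiring no training data (`build_iip_mask()`);
* **mask ingestion / CNN** — any external segmenter's binary mask is
  accepted (`read_rib_mask()`), and a small trainable U-net is included
  (`build_unet()`, `train_unet()`, `predict_mask()`).

The sequence labeler (`label_sequence()`) is agnostic to the mask's
provenance, which is the central design point: segmentation quality and
sequence logic are judged separately.

## The labeling model and its assumptions

A rib, in an axial stack windowed for bone, is a bright, elongated,
face-connected cluster of voxels. The labeler formalizes this:

1. **Region growing.** Starting from seed voxels found by scanning slices
   from the most superior slice in raster order, every foreground voxel's
   six-connected neighbourhood (the two neighbours along each of x, y, z)
   is examined and included while foreground remains — `grow_3d()`. Each
   maximal component is one candidate rib. On a full complement this
   yields 24 clusters.
2. **Ordering.** Because rib pairs enter the thorax superior→inferior,
   the order of *first appearance* (smallest slice index) equals the
   anatomical ordinal. Clusters first appearing on the same slice are
   ordered by the raster position of their seed, matching the scanning
   convention.
3. **Laterality.** Under radiological display (patient left at image
   right) a cluster whose centroid column lies beyond the midline is a
   left rib; ties go right. The midline is the mean detected vertebra-box
   center column when template detections are available, else the volume
   center. The paired volume is re-coded: left rib *i* → label *i*, right
   rib *i* → label *P + i* for *P* pairs, so the label set is exactly
   `{1..2P}` (24 on a full complement).
4. **Pairing.** Within each side, ordinal *i* is the *i*-th cluster in
   first-appearance order; pair *i* joins left-*i* with right-*i*.
   Pairing stops at the smaller side count; surplus clusters are reported
   `unpaired` with a warning rather than being forced into a pair, and
   more than 12 pairs flags the case (`too_many_pairs`) since a non-rib
   object must have been labeled.

Assumptions worth stating: the stack is axial with slice 1 most superior;
ribs do not touch each other (the vertebral column and sternum, which
would connect them, are removed before labeling); and every rib is
resolved as one connected component (a rib visible on only a single
noisy slice can be lost to the `min_cluster_size` guard).

## The IIP mask pipeline

`build_iip_mask()` runs five stages, in order. No stage ever *adds* a
foreground voxel, so the final mask is provably a subset of the
binarization.

1. **Windowing and binarization.** HU are mapped to 0–255 with window
   width/level 400/40 HU (bone emphasis), linear with half-up rounding
   and inclusive clamps; `binarize()` keeps pixels *strictly above* 140,
   the midpoint-plus of the display range. The threshold is a fixed
   constant with an override; a per-image mean mode was considered and
   rejected as less reproducible (the mean of a chest slice depends
   heavily on field of view).
2. **Vertebra detection.** `match_vertebra()` slides each template of a
   vertebra library over the posterior half of the slice (configurable to
   the whole slice) and minimizes the sum of absolute differences
   SAD(u, v) = Σ |I₁[u, v] − I₂[u, v]| over the template footprint. Ties
   break toward the smaller template id, then raster order. For binary
   images the score map is computed *exactly* via
   SAD = 255·(window_fg + template_fg − 2·overlap), with window counts
   from an integral image and overlaps from an FFT cross-correlation
   (every quantity is an integer multiple of 255, so rounding the FFT
   output is lossless); grayscale inputs fall back to direct summation.
   A detection is *reliable* iff its score is below the ceiling
   (default: half of `255 × template_foreground`); unreliable slices
   reuse the nearest superior reliable detection.
3. **Zero padding.** The detected vertebral region — the tight bounding
   box of the matched template's foreground, optionally expanded by
   `erase_margin` — is erased. The sternum faces the vertebra across the
   thorax, so its erase box is the vertebra box reflected across the body
   center row, sharing the vertebra box width. Its height is
   `sternum_scale` (default 2) times the vertebra box height: only the
   reflection center is inferred, so a taller box buys robustness to an
   imperfect reflection at no cost (no other bone lives on the anterior
   midline). The body center row is the midpoint of the foreground
   bounding box after excluding the posterior bed band — a pixel-mass
   centroid is dragged posteriorly by the vertebra and bed.
4. **Bed and noise removal.** Per slice: morphological opening with a
   disk (radius 1), removal of four-connected objects under `min_size`
   (20 px), and removal of objects whose bounding box touches the
   posterior border band (10 px) — the scanner bed is always the most
   posterior structure.
5. **Contact filtering.** 2D regions are linked across consecutive
   slices by pixel overlap into 3D objects (equivalently, six-connected
   components) and an object is kept iff, on its first slice of
   appearance, some pixel lies within Chebyshev distance
   `contact_margin` (3 px) of that slice's vertebra box. Ribs attach to
   the spine at their first appearance; clavicles and scapulae do not.
   The exclusion rule is applied to *tracked 3D objects* rather than to
   2D regions slice-by-slice: "first appearance" is only well defined
   for an object followed across slices, and a per-slice rule would
   delete every anterior rib section (which is far from the spine on its
   own slice).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| window width / level | 400 / 40 | HU | bone-emphasis display window |
| binarization threshold | 140 | gray level | above the display midpoint; bone only |
| in-plane target spacing | 0.798 | mm | cohort-unified pixel spacing |
| `erase_margin` | 0 | px | erase exactly the detected region |
| `sternum_scale` | 2 | × box height | robustness of the reflected erase box |
| `opening_radius` | 1 | px | speck removal without thinning ribs |
| `min_size` | 20 | px | sub-rib 2D fragments are noise |
| `bed_band` | 10 | px | posterior strip that only the bed touches |
| `contact_margin` | 3 | px | "touching the spine", tolerant of erasure |
| `min_cluster_size` | 30 | voxels | 3D noise guard; 0 restores strict behaviour |
| `max_pairs` | 12 | pairs | anatomical rib count |

All are configurable via `iip_config()` / `labeler_config()` or a YAML
config file (`load_iip_config()`).

## The synthetic phantom

No public CT accession accompanies the method, so `generate_phantom()`
builds a parametric thorax with voxel-level ground truth: by default a
512 × 512 × 56 stack at 0.798 mm in-plane / 3 mm slice spacing containing
twelve bilateral rib arcs, a vertebral column, an anterior sternum, a
soft-tissue body ellipse, a scanner bed strip and one clavicle-like
distractor; bone at 700 HU, soft tissue 40 HU, air −1000 HU, noise off.
Variants emulate the documented failure modes: `missing_rib` (the absent
or tiny 12th rib), `fused_pair` (adjacent true ribs converging near the
sternum and merging on axial slices), and distractor bones that a correct
pipeline must exclude.

Construction choices that make the phantom a *fair* test rather than an
easy one:

* each rib is a thin elliptical arc advancing one angular step per slice
  (overlapping windows guarantee face connectivity across slices), its
  most posterior voxels face-adjacent to the vertebral column on its
  first slice — exactly the property the contact filter and the
  first-appearance ordering rely on;
* every structure is rasterized as a dilation by the same 3 × 3 brush the
  default opening uses, so morphological cleanup is provably lossless on
  true structures and the pipeline can be held to *exact* voxel recovery;
* rib pairs occupy disjoint slice blocks and all pairs share one
  arc-radius function, so the fused variant's bridge voxels provably
  coincide across adjacent slices and no unintended rib–rib contact can
  occur; the generator validates component counts and structure
  disjointness and refuses to emit an invalid phantom.

What the phantom does **not** emulate: CT physics (beam hardening,
reconstruction kernels, partial-volume blur), cortical/trabecular
intensity structure, anatomical variability of arc shape, and contact
between ribs and genuinely adjacent bones (transverse processes,
costovertebral joints). A passing suite therefore demonstrates the
*contracts* of the algorithms — exact mask recovery, correct ordering,
correct failure taxonomy — not clinical-grade performance; the reported
clinical success rates are not reproducible from synthetic data and are
not asserted anywhere in the tests. The vertebral cross-section is
constant across slices, so the generated 15-template library varies only
in border width; real template libraries carry genuine shape variation.

## The CNN arm

`build_unet()` implements the classic U-shaped encoder–decoder with skip
connections in plain R (im2col convolutions, 2 × 2 max pooling,
nearest-neighbour upsampling followed by a convolution, sigmoid output,
binary cross-entropy, Adam). Defaults are the classic configuration —
depth 4, 64 base filters, batch size 8, epoch cap 300, early stopping on
a validation split — all overridable; the filter counts, loss and
optimizer are declared defaults, not values inferred from any reference.
It trains genuinely (the test suite drives a depth-2, 8-filter micro
configuration to held-out Dice > 0.8 on synthetic blob images within
seconds) but is sized for small images and CPU; for production
segmentation one would train externally and feed the mask in via
`read_rib_mask()`. Segmentation quality is scored by
`confusion_counts()` + `compute_metrics()` (Dice, precision, recall,
specificity, accuracy; positive = rib voxel; undefined ratios are `NA`,
never 0), with `kfold_split()` providing deterministic patient-level
folds.

## Evaluation and the error taxonomy

`case_success()` matches predicted clusters to truth ribs by voxel
overlap: a truth rib is covered by the cluster holding at least half of
its voxels (a visual-judgement criterion made operational; 50% is the
smallest fraction that at most one cluster can hold). A case succeeds iff
every truth rib is covered by a cluster with its correct ordinal and
side, one-to-one, and every cluster lies mostly on truth ribs. Failures
are classified exhaustively into three classes: `overlapped_pair` (one
cluster covers two ribs), `missed_rib` (a rib uncovered, or covered under
a wrong ordinal/side), `nonrib_labeled` (a cluster mostly off the ribs).
`success_rate()` aggregates cases into a percentage with a
normal-approximation 95% CI clipped to [0, 100]; the CI method behind
published intervals for such rates is generally unstated, so intervals
are reported but never asserted against external values.

## Numerical choices and degenerate inputs

* Indices are 1-based and boxes inclusive, per R convention.
* Window mapping rounds half-up (`floor(x + 0.5)`); clamps inclusive.
* Resampling: bilinear for intensity, nearest-neighbour for masks and
  labels (no new values); new dimensions `round(n·s/target)`; slice
  spacing never resampled; a volume already at target spacing is
  returned voxel-identical.
* Degenerate inputs: an all-air volume yields no reliable vertebra
  detection and errors or warns per `missing_vertebra` (returning an
  empty mask when warning); an empty mask labels to an empty report; a
  detection box at the slice border is clipped, never an error.
* Determinism: every stochastic element (phantom noise, U-net
  initialization and shuffling, fold assignment) is driven by an explicit
  seed through a local RNG that does not disturb the session's stream;
  the IIP + labeling pipeline is fully deterministic, bit-identical
  across runs.

## Problem sizes in the test suite

The suite exercises the full-scale 512 × 512 × 56 reference phantom once
(shared across the end-to-end checks) and uses a geometrically similar
160 × 160 × 56 twelve-pair phantom for the per-stage tests; oracle
cross-checks run on 100 random volumes up to 32 × 32 × 16 against an
independently implemented minimum-label-propagation component finder, and
the U-net smoke test trains the micro configuration on fifty 32 × 32 blob
images. These sizes are the package's own choice of a thorough but
desk-scale regression net.

## Known limitations

* DICOM series must be converted to NIfTI upstream; `read_ct_volume()`
  reads NIfTI only and assumes the package's axial orientation
  convention rather than reorienting from the header.
* The IIP route assumes the vertebral column is present and posterior;
  fields of view excluding the spine defeat it (by design, it then
  errors rather than guessing).
* Ribs that genuinely touch (severe crowding, fracture callus) merge
  into one cluster and surface as `overlapped_pair` failures — faithful
  to the method, not recoverable by it.
* The 11th/12th ribs' small cross-sections sit near the `min_size` /
  `min_cluster_size` guards; on marginal data those guards should be
  lowered (at the cost of noise sensitivity).
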