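---
title: "Compartment-level analysis of normal breast histology with nbtclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-level analysis of normal breast histology with nbtclassify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Normal breast tissue (NBT) on an H&E-stained whole-slide image is a
mosaic of three compartments: epithelium (the terminal duct-lobular
units, TDLUs), fibrous stroma, and adipose tissue. Quantitative analysis
of each compartment — and especially of lobules with their surrounding
peri-lobular stroma — requires first labelling every patch of a
gigapixel slide with its tissue class. `nbtclassify` implements that
pipeline end to end: stain normalisation, physical-size tessellation,
patch classification, whole-slide probability maps, lobule detection,
and QuPath-compatible export, together with the evaluation machinery
(per-class ROC/AUC, DeLong's test) needed to validate the classifier.

Because annotated NBT cohorts are access-restricted, the package ships a
deterministic synthetic H&E-like generator so every stage is exercised
and tested without downloading any image.

## The classifier

The model follows the transfer-learning pattern: a *frozen*
convolutional backbone extracts visual features; only a compact dense
head is trained.

* Head topology (fixed): global average pooling over the final
  convolutional activations → dense(F → 1024, ReLU) → dropout(rate 0.5)
  → dense(1024 → 512, ReLU) → dense(512 → 3, softmax). For a
  1280-channel backbone the head holds 1,838,083 trainable parameters.
* Training defaults (`train_config()`): categorical cross-entropy, Adam
  with learning rate 1e−5, batch size 16, 50 epochs, Xavier-normal
  initialisation. The epoch with the highest validation accuracy is
  kept. These defaults describe the full-scale protocol; the toy-scale
  synthetic runs in this package's tests use learning rate 1e−3 and
  10–15 epochs, which the small, cleanly separable synthetic task needs
  for Adam to traverse the same loss landscape in a few hundred steps.
* Augmentation (`augment_config()`): exactly six techniques —
  horizontal flip, rotation in (−40°, 40°), shift, shear, zoom, and
  additive channel shifts in [0, 10] intensity levels. Ranges the
  protocol does not fix are set to flip p = 0.5, shift ±10 % of the
  side, shear ±10°, zoom [0.9, 1.1], reflect fill; the channel shift is
  read literally as a positive offset drawn uniformly from [0, 10] per
  channel, clipped at 255. All six are composed into a single bilinear
  affine warp so that a neutral draw is exactly the identity.

### The packaged toy backbone

No pretrained network is required: the default backbone is a small
frozen conv stack (three 3×3 same-padding blocks, 16/32/64 channels,
He-normal seeded init, max-pooling after the first two blocks) whose
final 64-channel activation map plays the role of the "last
convolutional layer". Its GAP output passes through a *frozen
per-channel standardisation* (mean/sd fixed from the training features
at the start of training) before entering the head. This step is part of
the backbone design, not of the head: spatially averaged random-conv
features concentrate around a large common mean with a very small
between-class spread, and without rescaling the Xavier-initialised head
under 50 % dropout cannot pick the signal up, although the features are
linearly separable. Standardisation is the standard remedy when training
shallow heads on frozen features; its constants are frozen with the
backbone thereafter, and the CAM/Grad-CAM channel weights absorb the
1/sd factor so explainability remains consistent with the forward pass.

### Explainability

The two-hidden-layer head has no single class-weight vector, so classic
CAM does not apply directly. `cam()` therefore weights the final conv
channels by the corresponding column of the *linearised head* — the
product `W1 W2 W3` of the dense weight matrices with ReLU and dropout
dropped. `grad_cam()` is the standard formulation: channel weights are
the spatial mean of ∂(class logit)/∂A_k computed analytically through
the GAP and the ReLU masks active at the input; the heatmap is the
ReLU-ed weighted sum. Both are min-max normalised to [0, 1] and can be
bicubically resized to patch dimensions (bicubic is reserved for these
overlays; ordinary patch resizing is bilinear). For an input on which
every ReLU is active and the weighted sum is non-negative, the two
methods coincide — a property the tests pin to 1e−5.

Grad-CAM scores use the pre-softmax logit: softmax gradients saturate
when one class dominates.

## Stain normalisation

`reinhard_normalize()` transfers colour statistics in the decorrelated
log space: RGB (scaled to [0, 1], floored at 1/255 before the logarithm)
→ LMS via the published 3×3 matrix → log10 → lαβ. Per-channel means and
standard deviations (computed over *all* pixels — no background
masking) are matched to the reference and the map inverted with
clipping. Numerical choices:

* The colour space is the original lαβ (log-LMS) pipeline, not CIELAB.
* Inverse transforms use exact matrix inverses of the forward matrices
  rather than independently rounded published inverses; this keeps the
  self-normalisation round trip within one 8-bit intensity level.
* A degenerate source channel (sd = 0) maps onto the reference mean
  (scale factor defined as 0). With 8-bit quantisation the achieved mean
  lands within ~5e−3 of the target in lαβ units.

The packaged reference (`default_stain_reference()`) is computed at call
time from a fixed synthetic stroma tile, so no image file ships with the
package; any real reference can be substituted via `lab_stats()`.

Note a real limitation that the synthetic tests surface clearly:
per-tile Reinhard transfer equalises each tile's *global* colour
moments. Applied to single-class patches this removes most of the
between-class mean-colour signal, leaving texture and colour-distribution
shape as the discriminative cues. The classifier handles this (the
acceptance runs train on normalised patches and reach ≥ 0.99 held-out
accuracy), but colour-driven explainability heatmaps are crisper for
models trained on un-normalised patches, which is how the localisation
property is evaluated.

## Whole-slide pipeline

* `detect_foreground()` — tissue = (HSV saturation > 0.05) OR (grey
  < 220), followed by removal of components and filling of holes below
  5,000 µm², computed on a downsampled thumbnail. This is a deliberately
  simple packaged rule standing where a dedicated QC tool would run in
  production.
* `tessellate()` — patches have a fixed *physical* edge: 128 µm for the
  512-px model, 256 µm for the 1024-px model. native_px =
  round(target_um / mpp); at 0.25 µm/px the 128-µm cell is exactly
  512 px (no resize), at 0.5 µm/px it is 256 px and is resized up. The
  grid is anchored at the origin, edge remainders are dropped
  (floor arithmetic), and a cell yields a patch iff its foreground
  fraction reaches 0.5 (the protocol is silent on partial cells; 0.5
  excludes glass-dominated patches without fragmenting tissue edges).
* `classify_slide()` — every patch is normalised (when a reference is
  given) and classified; probability triples are written at their grid
  indices, so patch order is irrelevant; untessellated cells stay
  background.
* `probability_heatmap()` — R/G/B = 255·(p_epi, p_str, p_adi);
  background renders white; `smooth = TRUE` upscales the probability
  grid by corner-aligned bilinear interpolation, so un-smoothed cell
  colours are preserved at the corners.
* `confidence_filter()` — confidence is the maximum class probability;
  the fraction counts cells *strictly* above the threshold (typical
  operating points 0.7 and 0.99).

## Lobule detection

From the class map's epithelium layer (argmax class 0):

1. connected components at 8-connectivity (diagonal acinar continuity;
   4-connectivity is configurable),
2. remove components below `min_object_px` — 400,000 full-resolution
   pixels at 40×, 250,000 at 20×,
3. fill interior holes below `max_hole_px` (400,000); filled cells join
   the component and count toward its area; holes touching the map
   border are not interior and are never filled,
4. render the mask at the ×32 enlargement and trace component polygons.

Areas are measured in full-resolution-equivalent pixels
(cells × native_px²): under that unit a two-cell object at 512-px cells
(524,288 px) clears the 400,000 threshold while a single cell
(262,144 px) does not, which is exactly the "more than two epithelium
patches" calibration; the ×32 enlargement is treated as a rendering
device only. Peri-lobular regions come in two modes: `bbox` (default,
matching the two-box visualisation — the bounding box expanded by the
physical width, minus the lobule) and `dilation` (a morphological disc
ring on the enlarged mask). Width defaults to 250 µm.

## Evaluation

`roc_auc()` computes the tie-corrected Mann–Whitney AUC from midranks
with a threshold-sweep curve. Multiclass results are reported one-vs-rest
per class, scored by that class's softmax probability (the standard
reading when "class-specific AUCs" are reported without a scheme).
`delong_test()` implements the fast midrank formulation of DeLong's
test: structural components V10/V01 per score vector, covariance
assembled as S10/m + S01/n, two-sided p from the normal approximation
without continuity correction. Degenerate cases are defined explicitly:
identical score vectors give z = 0, p = 1; zero variance with unequal
AUCs reports a p-value at the machine floor. `group_metrics()` computes
per-group confusion/accuracy/AUC tables with optional per-class capped
resampling repeated under seeded control, mirroring confounder-style
analyses.

## The synthetic generator

`make_tile()` renders single-class tiles with morphology parameterised
in microns so the texture adapts to the requested resolution: epithelium
is a pale-purple base with dark haematoxylin-like nuclear clusters
(radius 3.5 µm, ~0.016 nuclei/µm²), stroma is an eosin-pink base with
oriented sinusoidal fibre bands (wavelength 24 µm), adipocytes are white
vacuoles (diameter 45 µm) with thin membranes on a hex packing. The
three palettes are pairwise separated by > 20 mean-RGB units, so a
nearest-centroid rule already classifies tiles at ≥ 80 % — the learning
task is well-posed by construction. Cohort-style stain variation is an
additive per-channel RGB shift applied after rendering with clipping.
Every generator draws from a per-object sub-seeded stream, so layouts
are stable under edits and all outputs are byte-identical per seed.

`make_slide()` lays out a white glass margin, a stroma matrix, one
adipocyte field, and n epithelium blobs (radius 220 µm by default,
~3.4 patch cells across, placed with ≥ 2 cells of clearance by a
restarted greedy search that fails loudly when the canvas cannot hold
the request). The truth map is the majority label per patch cell
(background when tissue < 50 %), and the polygon annotations are the
*same* geometry the textures were rasterised from, so annotations and
truth agree pixel-exactly. `make_class_map()` skips rendering entirely
and places epithelium components of requested cell counts (optionally
with a one-cell interior hole; the count then includes the hole) on a
probability grid — the direct fixture for lobule detection.

What the generator does *not* emulate: nucleus-level morphology,
staining gradients within a slide, scanner artefacts (pen, blur,
coverslip edges), mixed-class patches except at region boundaries, and
class imbalance. Passing tests therefore demonstrate the correctness of
the machinery and the recoverability of a well-posed task, not clinical
performance on real cohorts.

## Problem sizes and numerical choices

* Toy-scale studies: training 150 patches/class with 30/class validation
  and 50/class held-out, three replicate seeds; tiles are generated at
  256 px / 0.5 µm per px (the 128-µm field of view at 20×) and resized
  to the 64-px toy input — the same path tessellated slide patches
  take. Pseudo-slides are 4096 px (three lobules) for end-to-end runs
  and 2560 px (one lobule) for unit tests.
* Ties in argmax resolve to the lowest class index; best-epoch ties
  resolve to the earliest epoch.
* Patch grid cells are half-open `[x0, x0+S) × [y0, y0+S)` in 0-based
  full-resolution coordinates; the centre rule uses a
  boundary-inclusive even-odd test so a centre exactly on a polygon
  edge counts as inside; centres inside overlapping annotations of
  conflicting labels are dropped (single-label training contract).
* Class-map CSVs are written at fixed 6-decimal precision, making
  pipeline reruns byte-identical (verified through manifest md5s).

## Known limitations

* The toy backbone is a seeded random feature extractor; it is the
  correct stand-in for testing the training/inference machinery, but
  its features are far weaker than a pretrained network's, and nothing
  here speaks to accuracy on real H&E.
* Per-tile Reinhard normalisation discards global colour contrasts
  between single-class patches (see above); alternatives that estimate
  stain vectors rather than colour moments are out of scope.
* Lobule polygons at pinch points (diagonally touching cells under
  8-connectivity) self-touch at the shared corner; the even-odd region
  they enclose is still exactly the cell union.
* `read_annotations()` handles polygon features only (no ellipses or
  brush strokes) and QuPath GeoJSON, not binary `.qpdata` projects.
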