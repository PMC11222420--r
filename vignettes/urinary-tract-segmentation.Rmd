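---
title: "Two-stage urinary-system segmentation: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage urinary-system segmentation: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

On non-contrast abdominopelvic CT the ureters are 3–4 mm tubes whose
radiodensity is nearly identical to adjacent vessels and muscle. Kidneys and
the urine-filled bladder are large and relatively easy to delineate; the
ureters between them are the hard part — small (often 1–10 pixels in an
axial image) and easily confused with iso-dense tubular neighbours. `uroseg`
implements a two-stage pipeline for segmenting the five urinary-system
classes (kidney, proximal/middle/distal ureter, urinary bladder):

1. **ROI extraction.** The volume is resampled to 4 mm isotropic voxels,
   each axial slice padded/cropped to 128×128, and a two-class model
   segments kidneys and bladder. The axis-aligned bounding cuboid of that
   foreground — expanded by safety margins — defines the region of
   interest. The ureters are deliberately *not* used: anatomically they
   almost never leave this cuboid, and `audit_ureter_containment()` checks
   exactly that on every case.
2. **Fine segmentation.** The ROI is resampled to 0.7 mm in-plane (slice
   spacing is kept), and a five-class multi-decoder U-Net segments each
   axial slice through 128×128 windows.

## The model

The network is a U-Net variant with a shared residual encoder and one
*independent decoder per class* (`n_classes` parallel decoders of identical
structure). The encoder has four levels of 3/4/6/3 residual blocks with
128/256/512/1024 channels, separated by 2×2 stride-2 max-pooling. Each
decoder has three levels of 6/4/3 blocks with 1024/512/256 channels,
upsamples with 2×2 stride-2 *transposed convolutions* (which also halve the
channel count), and concatenates the skip feature from the corresponding
encoder level. Each decoder level carries a 1×1-convolution sigmoid side
head; the full-resolution heads, stacked across decoders, form the final
per-class probability map — the output resolution always equals the input
resolution, which matters for structures a few pixels wide.

Training uses deep supervision: every side output is upscaled bilinearly to
the input size and scored against its class target with

    Loss_DS(x_c, y_c) = BCE(x_c, y_c) + 1 − DICE(x_c, y_c)

summed with equal weights over classes `c` and decoder levels `l`
(`deep_supervision_loss()`). BCE is the per-pixel mean, so the loss
magnitude is invariant to window size. `DICE` here is the smoothed soft
Dice `(2Σpg + ε)/(Σp + Σg + ε)`, chosen for differentiability; the hard
coefficient `2|S∩G|/(|S|+|G|)` (`dice_coefficient()`) is reserved for
evaluation.

Rather than scanning every slice position, training windows are drawn from
the **cropable centre area**

    CCA(I) = { (x, y) : k/2 ≤ x < W − k/2,  k/2 ≤ y < H − k/2 },

at most 10 non-overlapping random centres per slice per epoch
(`sample_window_centres()`); the random placement doubles as augmentation.
At inference the slice is covered by a sliding window of the same size with
overlap 0.5 (stride k/2), probabilities are averaged over all windows
covering a pixel, then an argmax with a 50 % background threshold produces
exclusive labels, which are restored to the original grid by
nearest-neighbour resampling into the ROI box location.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| normalisation window | [−175, 250] HU → [0, 1] | soft-tissue window; out-of-range values clamp to 0/1 |
| coarse voxel size | 4 mm | stage-1 working resolution |
| ROI margins | 15 mm / 6 mm | box expansion along the major axis / elsewhere |
| fine pixel size | 0.7 mm | stage-2 in-plane resolution |
| window size `k` | 128 px | training crop and sliding window |
| overlap | 0.5 | sliding-window overlap (stride k/2) |
| max points/slice | 10 | CCA sampling budget per epoch |
| flip / shift / rotation | p = 0.2, 0.5, 0.1 | augmentations; shift ≤ 0.1 normalised units, rotation ±15° |
| `width_scale` | 1.0 | multiplies all channel counts; 0.0625 gives the desk-scale 8/16/32/64 model |

## Interpretation decisions

Several details are under-specified in the published description; the
package fixes them as follows and exposes switches where both readings are
defensible.

- **Margin direction.** The methods text puts the 15 mm margin on the
  anterior–posterior axis, the figure caption on the superior–inferior
  axis. The default is superior–inferior (`margin_axis = "z"`): the
  cuboid's craniocaudal faces are bounded by kidney top and bladder bottom,
  the surfaces most at risk of truncating the system; `margin_axis = "y"`
  selects the other reading.
- **Intensity-shift wording.** "Offset and probability of 0.1 and 0.5" is
  read as: with probability 0.5, add one uniform offset with |δ| ≤ 0.1
  (normalised units).
- **Flips and rotation are in-plane** by default: the model consumes axial
  slices, and out-of-plane flips would break slice semantics. `flip_3d`
  enables z-flips for 3D inputs.
- **Soft vs hard Dice in the loss.** The loss uses soft Dice
  (differentiable); evaluation uses hard Dice.
- **Equal loss weights** across classes and levels — the simplest faithful
  reading; the breakdown is reported per (class, level) so any reweighting
  is a one-line change.
- **Block internals.** Residual block = Conv3×3–Norm–ReLU–Conv3×3–Norm with
  identity shortcut (1×1 projection on channel change); a single 3×3 stem
  maps the input to the first encoder width; batch norm by default
  (`norm = "none"` available). These internals are package choices, not
  published facts.
- **Side heads** exist at decoder levels only (H/4, H/2, H), not at the
  bottleneck.
- **Optimiser** Adam, lr 1e-4, batch 16 by default (unstated in the source
  material); desk-scale runs in the tests use lr 1e-3.

## Numerical choices

- **Empty-vs-empty Dice is 1.0** in evaluation: a slice with no ureter
  correctly predicted empty is a correct result. In the loss the ε-smoothing
  handles the same limit.
- **CCA-empty fallback.** With k ≥ W (or k ≥ H) the CCA is empty by
  definition, yet ROI slices are routinely that small. The fallback is
  per-axis: an axis the window does not fit along contributes its single
  centred coordinate, while a free axis is still sampled — collapsing to
  one centred window only when both axes are degenerate. (Collapsing the
  whole slice to a single centred window whenever one axis is short would
  systematically exclude lateral anatomy — the kidneys — from training.)
- **Flush-edge sliding windows.** The last window of the stride grid is
  shifted to end exactly at the border, so every pixel is predicted without
  extra padding.
- **Argmax ties** break to the lowest class index; winning probabilities
  exactly at 0.5 stay foreground.
- **Batch-norm statistics refresh.** After very short trainings the
  exponentially averaged running statistics (momentum 0.1) lag the trained
  weights, and inference-mode forwards disagree grossly with training-mode
  behaviour. `train()` therefore ends with `refresh_bn_stats()`: the
  running statistics are recomputed as the equal-weight mean of batch
  statistics over recent training batches (the standard post-hoc refresh).
  At clinical training lengths this is a no-op in effect.
- **NIfTI headers are float32**; geometry read back is snapped to 7
  significant digits so common spacings (0.7, 1.5 mm) round-trip exactly.
- **Voxel-centre convention** everywhere: world(i) = origin + i·spacing;
  boxes voxelise to half-open index ranges; resampling fixes the leading
  world edge, so world coordinates are preserved across grids.

## The phantom generator: its world, and what a green test means

Clinical data for this problem are not distributable, so the package ships
a synthetic phantom generator (`generate_phantom()`, `generate_cohort()`)
whose *defaults state the emulated world*: 3 mm slice spacing (the finer of
the two source protocols; the spec range is 3–5 mm), 1.5 mm in-plane
spacing at desk scale, two ellipsoidal kidneys superiorly, a bladder
inferiorly, smooth spline-path ureters of 3–4 mm diameter descending
through a retroperitoneal fat sheath, and vessel-like tubular confusers of
similar radiodensity running alongside — the iso-density ambiguity the
method exists to resolve. HU levels (soft tissue ≈ 40, urine ≈ 15, fat ≈
−100, vessel ≈ 40, noise sd 10) are free parameters of a non-contrast scan,
not published facts. Ureter subclasses are split at two axial landmark
levels (the stand-in for the sacroiliac-joint margins) with a one-voxel
overlap slab, so the ground truth is genuinely multi-label, as in the
clinical labelling. Two properties hold by construction and are verified by
oracles in the tests: every ureter voxel lies inside the kidney+bladder
bounding cuboid (the containment property the ROI stage relies on), and
each ureter is a 26-connected tube from kidney to bladder.

The generator does **not** emulate reconstruction physics (beam hardening,
kernels), stones, hydronephrosis, anatomical variation beyond jittered
geometry, or partial-volume texture. A green end-to-end test therefore
establishes that the *pipeline machinery* — geometry, sampling, loss,
optimisation, assembly, restoration, scoring — is correct and that the
expected qualitative difficulty ordering (kidney easier than ureter)
emerges; it does not establish clinical performance, and the published
clinical Dice values are out of reach by design at desk scale.

## Desk-scale test regime

The full architecture at width 1.0 is far beyond a CPU test budget. The
tests exercise the genuine architecture in two reduced forms: the
*overfit sanity* uses the real 3/4/6/3 + 6/4/3 block structure at
`width_scale = 0.0625` (8/16/32/64 channels) trained on a single slice;
the *end-to-end* run additionally reduces the block counts to 1/1/1/1 +
1/1/1 (block counts are `model_config` fields) and trains a few dozen Adam
steps at lr 1e-3 on eight phantoms — enough for the class-difficulty
ordering to emerge, not for polished masks. Training-step counts and
strides in the tests are runtime budgets, not modelling claims.

## Known limitations

- Single-axial-orientation DICOM reading only (identity-like direction
  cosines); gantry tilt and non-axial acquisitions are rejected.
- No morphological post-processing (erosion/dilation/CRF) — deliberately
  out of scope, as in the source method.
- The backward pass is hand-written; it is verified against numeric
  differentiation in the tests, but only the layer types used here are
  implemented.
- Training is single-threaded and CPU-bound; the package is a faithful,
  testable reference implementation, not a performance port.
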