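---
title: "Classifying red blood cell motion in shear flow: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying red blood cell motion in shear flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcmotion)
```

## The measurement problem

Red blood cells (RBC) suspended in a viscous medium under low shear flow adopt
one of two motion regimes that report on their deformability. A highly
deformable cell *tank-treads*: its membrane rotates around the cell body while
the projected shape seen by a top-view camera stays essentially constant. A
poorly deformable cell *flips* (tumbles like a tossed coin), so its projection
oscillates between a full disc and a thin rod. In sickle cell disease the
fraction of tank-treading cells per acquisition is a candidate bedside marker:
it is stable between crises and drops days before a vaso-occlusive crisis.

Measuring the marker means classifying thousands of short per-cell videos
(6 to over 100 frames, 31×31 px after normalization) per acquisition, in the
presence of a dominant nuisance class: *unreliable* sequences (out-of-focus
cells, overlapping cells, partially cropped cells), outnumbering usable ones
by roughly 15–30×. The package implements the full pipeline:

1. **Trajectory extraction** — from a full-field movie to per-cell 31×31
   sequences (median background, variance-filter detection, left-to-right
   tracking, cross-correlation positioning).
2. **Sequence preprocessing** — bounding sequence length by `K` via uniform
   or structural-similarity downsampling, with end-padding for the
   fixed-size model.
3. **Two-stage classification** — stage 1 discards unreliable sequences
   (positive class *reliable*), stage 2 separates flipping from
   tank-treading (positive class *flipping*).
4. **Evaluation and the marker** — confusion matrices,
   accuracy/precision/recall/F1 (F1 the harmonic mean of precision and
   recall), and the per-acquisition percentage of tank-treading cells among
   reliable cells.
5. **A synthetic-data simulator** providing ground truth for every stage, so
   the pipeline is fully testable without clinical data.

## The two classifier families

Both stages are binary classifiers over grayscale frame sequences, trained by
minimizing mean categorical cross-entropy (one-hot truth) with Adam under a
triangular cyclical learning rate spanning 1e-4 to 1e-3 within each epoch,
and best-epoch selection on validation loss.

**Approach A — time as channels.** Sequences are brought to exactly `K`
frames (downsampling long ones, padding short ones with black frames at the
end) and stacked on the channel axis of a single CNN, so the first channel is
the first frame and so on. The backbone is ResNet-18-shaped: a 64-filter 7×7
stride-2 stem over `K` input channels, a 3×3 max pool, four stages of two
residual basic blocks with [64, 128, 256, 512] 3×3 filters (stride-2 stage
entry, 1×1 projection shortcuts at shape changes), global average pooling and
a 2-way softmax head. Two deliberate choices where the printed architecture
is silent or legacy: the ImageNet-era 1000-way dense layer is replaced by a
direct 2-way classification layer (the task is binary), and no normalization
layers are inserted — the network is implemented exactly as listed
(convolutions, ReLU, skip connections), which trains fine at 31×31 scale
with He initialization. Training is always from scratch: pretrained weights
do not exist for a `K`-channel grayscale stem.

**Approach B — convolutional recurrent network.** A small per-frame feature
extractor with weights shared across frames — conv 8×(3×3), conv 32×(2×2),
conv 64×(2×2) (all stride 1, padding 1, ReLU), max pool 3×3, conv 128×(3×3)
— is applied to each 31×31 frame. With those strides and paddings the
spatial trace is 31 → 31 → 32 → 33 → 11 → 11, so the flattened feature
vector has length 11·11·128 = 15488; no extra dense projection is added.
The feature sequence feeds a single-layer unidirectional GRU with 64 units
(PyTorch gate convention); the final hidden state — the *context vector* —
passes through dense layers of 64 and 2 neurons with softmax. Sequences of
any length are accepted, so no padding is needed. The bare "max pool 3×3"
in the layer table carries no stride; we use stride = pool size, the common
default when only a pool size is stated.

No deep-learning framework is attached: the layers, backpropagation, Adam
and the GRU are implemented in the package (R orchestration over
single-precision C++ GEMM kernels), which keeps the dependency footprint to
base R plus Rcpp/RcppArmadillo and makes training deterministic given a
seed.

## Class imbalance

Stage 1 faces a 15–30× unreliable:reliable imbalance, stage 2 a 5–15×
tank-treading:flipping imbalance. `balance_classes()` offers majority
down-sampling, minority up-sampling (originals plus sampled copies, so the
distinct-sequence set is unchanged), and the combined setting that maps
counts like (70 000 unreliable, 3 800 reliable) to (5 000, 5 000).
Balancing applies to training data only; validation and test sets always
stay in the real, imbalanced configuration.

## Similarity downsampling and SSIM

Human discrimination of the regimes rests on how the projection *changes*,
so when a sequence must be shortened the most redundant frames should go
first. `similarity_downsample()` iteratively scores every consecutive frame
pair with the structural similarity index and removes the second member of
the most similar pair until length `K`. Three points the procedure leaves
open were fixed as follows, all for determinism:

* remove the *later* member of the most similar pair (keeps the earliest
  appearance of each visual state);
* on ties, act on the earliest tied pair;
* after a removal, re-score only the two pairs adjacent to it — the removal
  creates one consecutive pair whose similarity was never measured, and no
  other pair changes. The test suite checks this lazy re-scoring against a
  brute-force replay that re-scores everything each iteration.

SSIM itself is the standard windowed luminance·contrast·structure form with
stabilization constants `C1 = (0.01·L)²`, `C2 = (0.03·L)²`, data range
`L = 1`, a uniform 7×7 window (clipped to the frame for smaller images) and
sample (n−1) variances, averaged over all valid window positions. No
installed package provides SSIM, so it is implemented here, with a
single-window hand evaluation of the formula as the test oracle.

Uniform downsampling keeps indices `round(i·(len−1)/(K−1))`, `i = 0..K−1`
(half-up rounding): endpoints are always retained, and for `len > K` the
kept indices are strictly increasing, so the result is a subsequence.

## The synthetic data generator

The simulator emulates exactly the statistical structure the pipeline
depends on, with ground truth at every level. Cells are anti-aliased
soft-edged ellipses (logistic edge profile, width 0.8 px) on a darker
background — the downstream stages need shape-over-time structure, not
bright-field pixel statistics. Defaults are the package's statement of the
study conditions:

* **Tank-treading**: constant semi-axes (radius 6 px, aspect ratio 0.75),
  orientation oscillating around the flow direction with 5° amplitude and a
  20-frame period.
* **Flipping**: apparent minor axis `radius · max(0.15, |cos(π t / P)|)`
  with tumbling period `P` = 12 frames by default — edge-on once per
  period; the 0.15 floor is the thickness of a disc seen edge-on.
* **Unreliable**: one of three artifact modes — Gaussian defocus blur
  (σ = 3), a second cell drifting through the crop, or a cell clipped by
  the crop border — mixed 40/30/30 when unspecified. The source material
  names the three artifact kinds but not their frequencies; the mixture is
  a stand-in, not a claim about clinical data.
* **Lengths**: log-uniform on [6, 100] for reliable classes (mean below
  40), up to 120 for unreliable ones; nothing shorter than 6 frames is
  produced, matching the extraction-stage discard rule.
* **Movies**: cells enter at the left edge and cross at constant per-cell
  speeds (2–5 px/frame), so faster cells can overtake slower ones; the
  background is a smooth illumination field (gentle horizontal gradient
  plus a wide vignette) with Gaussian pixel noise; ground-truth tracks
  record every frame in which the cell's full extent lies inside the field.

The generator's contract includes label separability: with low noise and no
artifacts, the apparent-width time series of a flipping sequence has a
coefficient of variation above 0.2 while a tank-treading one stays below
0.05. Tests assert this, and the learning-recovery checks rely on it.

What the simulator does **not** emulate: real bright-field point-spread
functions and halos, membrane mechanics, hydrodynamic interactions,
intensity statistics of the clinical camera. Passing tests therefore show
that the pipeline's machinery is correct and can learn the motion/artifact
structure it targets — not that clinical performance numbers are
reproduced.

## Trajectory extraction: numerical choices

* "100 random frames equally distributed" for the median background is read
  as stratified random sampling: the movie is cut into 100 equal bins and
  one seeded-random frame drawn per bin (all frames when the movie is
  shorter).
* Detection applies a 5×5 local-variance filter to the background-subtracted
  frame. The threshold is Otsu's, floored at 8× the median of the variance
  image: cells are sparse, so the median sits at the noise level, and the
  floor keeps pure-noise frames empty. The binary mask is morphologically
  closed (5×5 box) and hole-filled before labelling, because the variance
  response is strongest at object rims — an edge-on flipping cell would
  otherwise split into two lobes. Components under 20 px or touching the
  field border (partially visible cells) are discarded.
* Linking is greedy and frame-to-frame under the acquisition convention:
  left-to-right motion with steady speed. A link needs `dx > 0`, a
  y-displacement within 6 px, and — once a running mean x-step exists —
  agreement with it within 25% (with a 2 px absolute slack for pixel
  quantization); a track's first link is exempt but bounded by 15 px.
  Detections whose bounding boxes overlap another detection are dropped
  before linking (`drop_overlap_frames`, default on): momentary overlap
  during overtaking yields a merged blob whose position belongs to neither
  cell.
* Position refinement cross-correlates background-subtracted crops of
  consecutive frames. Both crops are anchored at the previous *detected*
  centroid, so each step is tied to an absolute position and integer-shift
  errors cannot accumulate along the track; without background removal the
  static illumination field would pin the correlation peak at zero shift.
  Shifts are limited to half the crop size; positions whose crop would
  leave the frame are clamped and flagged.
* "Normalized to 31×31" is implemented as a fixed 31×31 crop centered on
  the refined position, with a bilinear resize only when a detection's
  bounding box exceeds the crop. Intensity is min-max rescaled once per
  sequence — per-frame rescaling would erase the brightness dynamics that
  distinguish flipping.

## Problem sizes used by the tests and the acceptance script

The desk-scale checks are sized so that every stage runs from scratch in a
test session: the learning-recovery check trains both families on a
separable synthetic two-class set of about 500 training and 200 validation
sequences (7 acquisitions, split 5/2) with default lengths and noise, batch
size 16, six epochs for the fixed-size CNN and two for the recurrent
model — both families reach validation F1 ≥ 0.9 well inside the 20-epoch
envelope, and a label-shuffled control stays at chance. Batch size 16
rather than the full-scale default of 64 simply gives these small sets
enough optimizer steps per epoch.

The acceptance script's end-to-end cascade uses a 9-acquisition synthetic
cohort of 180 tank-treading / 30 flipping / 1200 unreliable sequences
(5/2/2 acquisition split). The unreliable:reliable ratio there is ~6×
rather than the clinical 15–30×: at this size a 15× ratio would leave too
few reliable sequences per held-out acquisition for the marker percentages
to have useful granularity. Stage 1 trains the recurrent model (K = 50,
uniform sampling, combined balancing to 80/80, 7 epochs); stage 2 trains
the fixed-size CNN (K = 20, similarity sampling, minority up-sampling,
12 epochs) on ground-truth reliable training sequences. During the stage-1
epoch loop, best-epoch selection uses a fixed subsample of the validation
acquisitions (all reliable plus 60 unreliable sequences); every reported
metric is computed on the full, untouched splits. Marker estimates are
reported over ground-truth-reliable test sequences, keeping the comparison
to the ground-truth ratio free of stage-1 selection effects.

## Known limitations

* The networks train in float32 without normalization layers; very deep
  training runs (hundreds of epochs) were not a design target.
* Position refinement is integer-shift (no sub-pixel interpolation), bounded
  by ~1 px quantization per frame; this suffices for 31×31 crops.
* The tracker is single-hypothesis and never bridges detection gaps; a cell
  lost for one frame starts a new track, which is then subject to the
  6-frame discard rule.
* The marker's clinical thresholds (crisis prediction) are out of scope; the
  package reports the per-acquisition percentages and their errors only.
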