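---
title: "Sequence-aware multi-scale attention segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-aware multi-scale attention segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac MRI produces ordered stacks of 2D slices. Segmenting the left
atrium in such stacks is hard for four reasons that shape everything in
this package: (1) the target is *continuous across adjacent slices*, so a
slice cannot be treated in isolation without discarding information;
(2) its cross-sectional *scale varies strongly* from slice to slice —
small caps at the ends of the stack, a large body in the middle; (3) its
*contrast against surrounding tissue is low*; and (4) it occupies *well
under ten percent of the pixels*, a severe foreground/background
imbalance.

`seqseg` implements a segmentation network built around those four
properties, together with the preprocessing, losses, metrics, training
protocol and a synthetic phantom generator that reproduces the same four
properties so the entire pipeline can be exercised end to end on a
laptop-scale CPU budget.

## Model

### Per-slice CNN

Each slice passes through a U-shaped encoder–decoder. The encoder is a
residual bottleneck network emitting five skip feature maps of 64, 256,
512, 1024 and 2048 channels at strides 2–32 (a `reduce` factor divides
all widths for desk-scale work; the depth is one bottleneck block per
stage, which preserves the width/stride contract while keeping
from-scratch CPU training feasible). The decoder repeatedly upsamples
(bilinear, followed by a 3×3 convolution) and concatenates the matching
skip map without any cropping, ending at full input resolution.

### Multi-scale fusion attention on the skips

Every skip connection (configurable; by default every level whose
spatial size admits the largest pyramid grid) passes through a fusion
module with two parts:

* **Dual pyramid pooling.** The map is pooled onto 1×1, 2×2, 4×4 and 6×6
  grids twice — once with average pooling (context) and once with
  maximum pooling (detail/boundaries). Each pooled map is projected to
  C/4 channels by a 1×1 convolution and upsampled back; the four average
  maps and the four maximum maps are stacked to C channels each, summed,
  and concatenated with the input, giving 2C channels.
* **Dual attention.** On the fused map, *position attention* reweights
  every pixel by its softmax-normalized similarity to every other pixel
  (`S[j, i] = softmax_i(B_i · C_j)`, output `α Σ_i s_ji D_i + A_j`), and
  *channel attention* does the same across channels using the raw
  channel vectors (`X[j, i] = softmax_i(A_i · A_j)`, output
  `β Σ_i x_ji A_i + A_j`). Both scales α and β start at exactly 0, so a
  freshly initialized module is the identity — training decides how much
  attention to mix in.

Two open points were fixed as package design choices. The two attention
branches are combined by elementwise *mean* rather than sum: each branch
is a residual off the same fused map, and the mean keeps the
initialization identity exact (at α = β = 0 the module output is the
pyramid-fused map through the final 1×1 projection, with no silent factor
of two). And because the pairwise position map is quadratic in the pixel
count, position attention computes it on an average-pooled copy capped at
32×32 and upsamples the attention term; below that size the computation
is exact.

### Bidirectional convolutional GRU across slices

Slice order matters in both directions, so the decoder outputs of a
T-slice sequence (T = 8 by default) run through a convolutional GRU —
the textbook GRU with every dense product replaced by a same-padded 3×3
convolution — once forward and once backward. The two hidden states per
step are concatenated (2C channels), passed through a 1×1 convolution to
the class count, and softmaxed per pixel. Hidden width equals the input
width, initial states are zero.

### Loss

Training minimizes soft Dice loss plus focal loss. Dice loss
`1 − (2Σpg + s)/(Σp + Σg + s)` directly optimizes overlap and is
insensitive to the foreground fraction; focal loss
`−αy(1−p)^γ log p − (1−α)(1−y)p^γ log(1−p)` down-weights easy background
pixels. Defaults α = 0.25, γ = 2 follow the original focal-loss
recommendation, and the Dice smoothing constant is 1e-6; all three are
configurable. Predictions are clipped to [1e-7, 1 − 1e-7] before logs.
Positions added by sequence padding carry zero weight in both terms.

## Preprocessing conventions

Volumes are stored (slice, row, col) with the scan axis first (1-based,
per R convention). Intensities are min-max normalized per volume to
[0, 1] — bounded inputs without dataset statistics. During training,
slices without any foreground are excluded; at inference every slice is
kept. Images resize bilinearly, masks by nearest neighbour so they stay
binary. Slices group into non-overlapping windows of T; a final short
window repeats its last slice, and the padded positions are recorded and
excluded from loss and metrics. Mask volumes coded 0/255 are remapped to
0/1 on load.

## Training protocol

Three stages, mirroring how the architecture decomposes: (1) the
per-slice CNN trains alone with a temporary static 1×1 class head;
(2) the full network is assembled, every CNN parameter is frozen
(verified bitwise by the test suite), and only the recurrence and its
head train; (3) everything unfreezes and fine-tunes at a smaller rate
(default 0.001). The step schedule multiplies the learning rate by 0.5
every 10 rounds ("rounds" are epochs here, configurable); a cosine
schedule from 0.01 down to 0.0001 is available as the alternative.
Momentum SGD (0.9) is the protocol default; Adam is available and is
what the compact demonstrations use, because at the reduced scale plain
SGD tends to settle into the all-background solution that the class
imbalance makes locally attractive.

## The phantom generator

`generate_phantom()` emulates the four data properties above: a single
elliptical target whose area follows a half-sine profile across slices
(smallest-to-largest area ratio > 3), whose center performs a small
random walk (adjacent-slice mask IoU stays above 0.5), at low contrast
(0.15 by default) over a flat background, with additive Gaussian noise,
with per-slice foreground capped below 10% (0.08 by default with
discretization head-room), and with distractor blobs drawn at
intensities within the contrast band of the target. Distractors are
placed independently per slice — they emulate other tissue
cross-sections entering and leaving the imaging plane, and their lack of
continuity is exactly what the recurrence can exploit — and they never
overlap the target, keeping ground truth unambiguous. The target's
minimum area is floored at a fifth of its peak so neighbouring end
slices never double in area, which is what the continuity property
requires. Everything derives from one seed; a dataset derives per-volume
seeds from a master seed and splits 4:1 into training and validation.

What the phantoms do *not* model: MRI physics (coil inhomogeneity,
partial volume, motion), anatomical shape, inter-tissue texture. Tests
passing on phantoms therefore demonstrate that the architecture, losses,
optimizer and metrics function and interact correctly — not that the
network reaches clinical accuracy on real atrial MRI, which requires the
full-scale datasets and GPU budgets out of scope here.

## Numerical and engineering choices

* The network runs on a small reverse-mode autodiff tape written for
  this package (R arrays + compiled im2col/col2im kernels; convolution
  is one matrix product). Every primitive's gradient is checked against
  central finite differences in the test suite.
* He-normal initialization, biases zero; no normalization layers — at
  the reduced scale they add variance without helping, and their
  omission keeps runs bit-reproducible from one seed.
* Binarization uses a strict `p > threshold` rule (default 0.5), so a
  tie goes to background, deterministically.
* Dice/IoU with two empty masks is defined as 100% (perfect agreement);
  Hausdorff distance with an empty mask is reported as missing, never as
  a sentinel value. Hausdorff is the exact maximum (not a percentile),
  computed blockwise from coordinate sets, optionally scaled per axis by
  voxel spacing.
* Max pooling breaks ties by first index; adaptive pooling partitions
  the grid with floor boundaries, so every pixel belongs to exactly one
  cell.

## Desk-scale study conditions

The compact experiments (`overfit_experiment()`,
`ablation_experiment()`) use 32×32-pixel slices, 8-slice phantoms,
sequence length 4, a width-reduced network (factor 16, ~0.38 M
parameters) and step-decayed Adam (0.005/0.002/0.001 over 200 steps for
the overfit demonstration; 0.003 for 60 steps per ablation arm). These
sizes were chosen so a single run finishes in minutes on one CPU core
while still exercising every architectural component; the vignette-level
claim tied to them is directional (training works; the recurrence helps
on continuity-rich data), not a magnitude.

## Known limitations

* Single foreground class (background/foreground); no multi-structure
  output head.
* One bottleneck block per encoder stage rather than the full 50-layer
  depth; pretrained encoder weights are not shipped, though a checkpoint
  hook can load externally supplied parameters.
* NRRD support covers the common scalar attached-header case (raw/gzip,
  little-endian).
* The Hausdorff aggregation is 3D per volume by default (per-slice
  breakdown available); whether to aggregate in 2D or 3D is a reporting
  convention the user can choose.
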