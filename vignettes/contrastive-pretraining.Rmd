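---
title: "Contrastive self-supervised pretraining for subtomogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive self-supervised pretraining for subtomogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryocssl)
```

## The problem

Cryo-electron tomography images macromolecular complexes in their native
cellular context, but annotating subtomograms (small cubic subvolumes, each
centred on one particle) is expensive: classification labels are scarce while
unlabelled subtomograms are plentiful. `cryocssl` implements a pipeline that
spends the unlabelled volumes on contrastive self-supervised pretraining of a
3D convolutional encoder and then fine-tunes the pretrained weights on
whatever labelled fraction is available.

## The contrastive model

Two stochastic augmentations of one subtomogram form a *positive pair*
$(x_q, x_k)$; views of different subtomograms are negatives. A query encoder
$f_q(\cdot;\theta_q)$ and a key encoder $f_k(\cdot;\theta_k)$ map views to
L2-normalized embeddings $q$ and $k$. For a batch of positive pairs and a
FIFO dictionary of $K$ historical keys $k_i$, the loss is the softmax
cross-entropy over $1 + K$ temperature-scaled similarities,

$$
\mathcal{L} \;=\; -\frac{1}{B}\sum_j \log
\frac{\exp(q_j \cdot k_j/\tau)}
     {\exp(q_j \cdot k_j/\tau) + \sum_i \exp(q_j \cdot k_i/\tau)},
$$

implemented exactly as printed (the positive term appears in the
denominator, so the uniform-similarity value is $\ln(K+1)$ — a closed form
the tests assert). The key encoder receives no gradients; after every
optimizer step on $\theta_q$ it takes the momentum update
$\theta_k \leftarrow m\,\theta_k + (1-m)\,\theta_q$, and the batch of fresh
keys replaces the oldest block of the queue. An in-batch variant
(`pretrain_simclr()`) uses a single encoder and the $2(B-1)$ other in-batch
views as negatives, with no queue.

Embeddings are L2-normalized before the dot product: a temperature of 0.2
only has its intended sharpness on the unit sphere. The loss gradient flows
only through $q$; keys are detached and re-normalized, which is the
momentum-encoder contract.

## The encoder

`build_encoder()` realizes a residual-block 3D CNN: a 3×3×3 convolutional
stem; residual stages of `[conv → ReLU → conv]` with an identity skip
(stride 1 throughout), each followed by 2×2×2 max pooling; a concatenation
junction of the last two same-shaped filter maps; then a shared fully
connected layer (default width 1024) feeding an embedding head (`FC-L`,
default L = 128) and a softmax classification head. The published figure of
the reference architecture does not pin down a machine-readable layer list
(its pooling caption is internally inconsistent), so the stage count, width
and the concatenation junction are configurable; every named ingredient is
present.

Two initialization choices matter because the network has **no
normalization layers** (deliberate: evaluation-mode forwards are bitwise
deterministic, and the momentum rule covers every parameter without special
handling of running statistics):

* the second convolution of each residual block starts at zero, so each
  block is the identity at initialization and activation variance does not
  compound across depth;
* the classification head starts near zero (initial cross-entropy is
  $\ln C$), while the embedding head keeps full Xavier scale — a near-zero
  embedding head lets a constant bias dominate the normalized direction and
  collapses the contrastive representation (we observed exactly this
  failure).

A 3D Grad-CAM (`gradcam()`) weighs the last residual stage's channel
activations by spatially averaged class-score gradients, rectifies, and
trilinearly upsamples to the input grid for qualitative inspection.

## The augmentation pipeline

`augment_policy()` encodes the volumetric positive-pair pipeline: a random
resized crop applied with probability 0.5 (crop scale drawn from [0.5, 1],
interpreted as the retained *volume fraction*, crop side
$s\cdot\mathrm{scale}^{1/3}$ — the 3D analogue of area-fraction cropping;
a side-fraction interpretation is available via `crop_scale_mode`), then a
random affine with probability 0.5: rotation about the z axis uniform in
±45°, in-plane (x, y) translations up to 0.1 of the side, isotropic scaling
within 1 ± 0.1. The fixed composition order is scale → rotate → translate in
one trilinear resampling pass with zero fill; grid-aligned transforms
(identity, 90° multiples, integer shifts) are exact, which is what the
oracle tests exploit. The two views draw their gates independently;
augmentation never consults labels. Photometric jitter, blur, elastic and
bias-field transforms are deliberately absent (destructive at these volume
sizes), as is CTF/MTF corruption (an upstream reconstruction property, not
a view augmentation).

## The synthetic generator

`generate_dataset()` emulates the statistical structure of simulated
subtomogram benchmarks without any external data: a centred target
macromolecule in a crowded neighbourhood, tomographic missing-wedge
corruption, and calibrated Gaussian noise. Defaults mirror the simulated
study datasets: 10 classes × 500 volumes of side 32, SNR ∈ {∞, 0.05, 0.03},
60:20:20 train/validation/test split (per-class seeded shuffle, contiguous
partition, so all splits stay class-balanced); the real-data shape
(7 classes × 400 at 28³, 3:1:1) is one configuration away.

Each class is a rigid parametric motif with two parts:

* a **rotation-invariant radial profile** — a bank of near-orthogonal slots
  (a central Gaussian core and three well-separated Gaussian ring radii at
  0.12/0.18/0.24 of the side) of which the class activates the subset given
  by the nonzero 4-bit code of its index, with energy-balanced,
  class-modulated amplitudes. Codes overlap only partially between classes,
  which structurally bounds pairwise correlation: the canonical motifs of
  the default 10 classes stay below 0.9 normalized cross-correlation. This
  mirrors how real macromolecules differ first in size, compactness and
  radial mass distribution.
* **anisotropic decorations** — a handful of smaller off-centre Gaussian
  blobs with fixed relative geometry, which make the motif pose-sensitive.

Poses are uniform random rotations (quaternion draw) plus a small
translation (up to 1% of the side), modelling residual particle-picking
offset; subtomogram extraction centres particles much better than the
"anywhere in the central third" bound the manifest format permits, and
centroid separability of raw voxels — which the generator must provide to
be a usable testbed — degrades quickly with whole-voxel jitter. Neighbours
are motifs of random class and pose with centroids outside the central
third; they may overlap the target (that crowding is the stated challenge).

The missing wedge zeroes every 3D Fourier coefficient whose direction lies
within `wedge_half_angle` (default 30°, the conventional ±60° tilt range) of
the beam axis; the mask is symmetric under $k \to -k$ so the output stays
real. One discrete-geometry caveat: the $k_x = 0, k_z \ne 0$ plane (the
never-tilted axis) lies inside the wedge for *every* positive angle, so as
the angle shrinks the zeroed set converges to that plane, not to the empty
set. SNR is defined as Var(signal)/Var(noise) — the common cryo-ET
convention — and noise is added after the wedge, which keeps the empirical
SNR of generated volumes within a few percent of the configured value (the
calibration test demands 5%).

What the generator does **not** emulate: electron-optics contrast transfer
(CTF/MTF), non-Gaussian detector noise, structural heterogeneity within a
class, and density maps of real macromolecules. Tests passing on this
generator therefore demonstrate that the pipeline's machinery is correct
and that its qualitative behaviour (pretraining benefit under label
scarcity) reproduces — not that any particular accuracy level transfers to
real cryo-ET data.

## Semi-supervised protocol

`subsample_labels()` flags a stratified labelled subset of the training
split (largest-remainder apportionment across classes — at 25% of a
balanced 10 × 300 training set, exactly 75 per class). Stratification is a
design choice over global uniform sampling: it removes a variance source
and guarantees every class survives at 25%. `finetune()` trains the whole
encoder end-to-end (no frozen layers) with cross-entropy, SGD and a cosine
learning-rate schedule, and returns the epoch with the best validation
accuracy (ties to the earliest epoch). `run_grid()` sweeps methods × label
fractions with `n_runs` repeats, resampling the labelled subset with each
run's seed so the reported standard deviation reflects subset and
initialization variance together. `compare_methods()` is the two-tailed
pooled-variance Student's t-test (Welch via a flag).

## Desk-scale configuration

The package defaults are the published operating point: queue 128 (64 for
the smaller real-data shape), momentum 0.999, temperature 0.2, Adam at
lr 1e-4 / weight decay 1e-4 / batch 16 / 200 epochs for pretraining; SGD
with cosine decay at lr 5e-4 / 50 epochs for fine-tuning.

The tests and the acceptance script run a scaled-down experiment — 3
classes, 150 volumes at 16³, SNR 0.5, crowding 1–3 neighbours, MoCo 20
epochs, fine-tuning at 25% and 100% labels, 3 repeats — chosen to finish in
minutes on one CPU. Three settings are scale-adapted, for reasons worth
recording:

* **queue 32**: the queue cannot exceed the 90-volume training split and
  must stay divisible by the batch size (block-aligned FIFO);
* **key momentum 0.9**: 20 epochs × 5 batches is ~100 optimizer steps; at
  m = 0.999 the key encoder would still be essentially its random
  initialization when training ends. m = 0.9 gives the same *relative*
  averaging horizon (tens of steps) that 0.999 gives a run of tens of
  thousands of steps;
* **fine-tune lr 2e-3** (cosine, 15 epochs): at 90 training volumes the
  published 5e-4/50-epoch budget leaves the randomly initialized baseline
  visibly undertrained, which would flatter pretraining; 2e-3 trains the
  clean separable control to 100% test accuracy from random init.
  Pretraining itself keeps the published Adam lr 1e-4 — at desk scale
  larger rates let the encoder memorize instance noise, which is visible as
  embeddings less class-informative than a random encoder's.

`tiny_mode` of `encoder_config()` (2 stages, 16 filters, fc 128, L = 32,
pooled stem) is the matching encoder geometry, ~300k parameters.

## Numerical choices and degenerate inputs

Trilinear (order-1) interpolation with constant-zero fill everywhere a
volume is resampled; first-maximum tie-break in max pooling and in argmax
predictions; log-sum-exp stabilization in every softmax; constant volumes
z-score to all-zeros; an all-rectified Grad-CAM map returns zeros flagged
`all_zero`; a labelled fraction that would empty a class is an error, as is
a queue smaller than the batch. All stochastic entry points take a seed and
reproduce bit-identically under it; gradient correctness of the hand-rolled
backpropagation is pinned by finite-difference checks in the test suite.

## Known limitations

* The encoder is a faithful-in-spirit reconstruction, not a bit-exact copy
  of the reference architecture (whose published figure is not fully
  specified); SwAV-style clustering pretraining is out of scope.
* Training is single-threaded CPU R + BLAS; the full published operating
  point (200 epochs on 3000 volumes of side 32) is possible but slow —
  the package is tuned for method correctness and desk-scale experiments.
* Volumes are stored one-per-file as MRC mode 2; there is no HDF5 container
  backend.
* The pretraining-benefit experiment is stochastic; at desk scale its
  margin (several accuracy points at 25% labels) is reproducible in the
  mean over repeats, not guaranteed per individual seed.
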