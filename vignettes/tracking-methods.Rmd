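---
title: "Tracking keypoints in deformable 2D/3D videos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking keypoints in deformable 2D/3D videos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastrack)
```

## The problem

Fluorescence recordings of moving, deforming tissue — neurons in a crawling
worm, cells migrating during development — pose a multiple-object-tracking
problem with unusual structure: the objects are near-identical bright blobs
in a mostly empty volume, their motion is strongly but not rigidly
correlated, and ground-truth labels are expensive (a human annotating a few
hundred cells in one volume can take an hour or more). elastrack follows the
registration-based school of tracking: a fixed set of user-annotated
keypoints is carried through the video by directly optimizing, frame by
frame, a differentiable objective built on the image itself, so that a
handful of fully annotated *reference frames* — rather than a training
corpus — is the only supervision required.

## The objective

For a child frame $c$ with keypoint positions $\rho_i$ (the optimized
variables), the tracker minimizes

$$L = \lambda_R L_R + \lambda_N L_N + \lambda_D L_D + \lambda_T L_T$$

* **Registration** $L_R = \sum_i \left[1 - \mathrm{corr}\!\left(D(I^{(r)},
  \rho_i^{(r)}),\; D(I^{(c)}, \rho_i)\right)\right]$: each keypoint carries a
  small image descriptor $D$ — a $d \times h \times w$ lattice of
  multilinearly interpolated intensities centered on the keypoint — and is
  matched against the descriptor sampled at its annotation in the reference
  frame by Pearson correlation. Correlation makes the term invariant to
  gain and offset, which suits ratiometric and photobleaching data but also
  means blob *brightness* alone cannot disambiguate two keypoints; the
  surrounding context inside the descriptor does that.
* **Spring network** $L_N = \sum_{ij} k_{ij}\,|d_{ij}^{(c)} -
  d_{ij}^{(r)}|\,/\,d_{ij}^{(r)}$: every keypoint is connected to its
  `j_neighbors` nearest neighbors in the reference configuration, and edges
  penalize the relative change of their length. The term is invariant to
  global rigid motion and encodes "tissue moves together" without a
  skeletal model. With two or more references the stiffness $k_{ij}$
  becomes a correlation-like measure (axis-averaged covariance of the two
  keypoints' displacements across references, normalized by the geometric
  mean of their variances, clipped at zero) so springs between
  independently moving keypoints are weakened or cut.
* **Detection** $L_D = \sum_i (1 - C(I^{(c)})[\rho_i])$: an identity-blind
  feature-probability map $C$ pulls keypoints onto nearby detected
  features. $C$ is produced by a deliberately small convolutional combiner
  (a $1{\times}1$ channel-mixing layer, ReLU, one $3{\times}3({\times}3)$
  convolution, sigmoid; on the order of $10^2$ parameters) whose inputs are
  classical detector responses — Laplacian-of-Gaussian, difference of
  Gaussians, Richardson–Lucy deconvolution, percentile-normalized
  intensity. Training on a single fully annotated frame suffices; when one
  input channel already matches the target, training amplifies it and
  suppresses the rest.
* **Temporal smoothness** $L_T = \sum_i \sum_{t=c-\epsilon}^{c+\epsilon}
  \left|I^{(t)}[\rho_i^{(t)}] - I^{(c)}[\rho_i^{(c)}]\right|$: a
  zeroth-order penalty on the intensity sampled at the keypoint across a
  $\pm\epsilon$ frame patch ($\epsilon = 2$ by default). Because it
  presumes approximate registration of the neighboring frames, it is
  applied as an optional refinement pass after the main pass, and its
  gradient only updates the center frame.

All four terms are differentiable in the keypoint positions; gradients flow
through the multilinear interpolation, the descriptor blur, and the
correlation analytically (no autodifferentiation framework is used — the
chain rule is implemented explicitly, with the sampling hot path in C++),
and positions are updated by Adam.

## Frame ordering: references, branches, learning rates

Reference frames should span the recurring postures of the recording. The
package computes a similarity distance between every pair of frames (one
minus the Pearson correlation of standardized 32×32 maximum-projection
thumbnails) and recommends references by PAM k-medoids (greedy build plus
best-improvement swaps; the score — mean distance of frames to their
nearest medoid — is non-increasing over swaps and ties break toward lower
frame indices for reproducibility).

The remaining frames are sorted into parent–child *branches* rooted at the
references. Two modes exist: `chronological` (each reference grows forward
and backward chains until it meets another branch; right for slow or
non-repeating motion) and `similarity` (greedily attach the unassigned
frame closest to any assigned frame; right for periodic locomotion, where
it clusters similar postures around the reference that represents them).
The child is initialized at its parent's tracked positions, and the
per-frame learning rate is scaled by a clamped linear function of the
parent–child similarity distance (`lr_floor` at distance zero, saturating
at `lr_ceil`), so similar pairs make conservative updates and dissimilar
pairs can travel.

## Partial supervision

A partially annotated frame contributes twice. Its annotated keypoints are
*pinned*: excluded from the update step but still exerting spring forces,
pulling their neighbors toward plausible configurations. And before
optimization, the displacements between the annotations and the same
keypoints' parent coordinates are interpolated into a flow field (a
thin-plate radial-basis interpolant, kernel $r^2 \log r$ on the 3D
control distance with a linear polynomial part) that initializes the
*unannotated* keypoints closer to their true positions. With one control
point the field is constant; the polynomial part is restricted (by pivoted
QR) to the directions the control points actually determine, so a constant
displacement observed at a few controls extrapolates as a constant shift
rather than an arbitrary plane.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `grid_shape` | 5×25×25 px | descriptor large enough to carry neighborhood context at the native scale of a few-hundred-pixel frame; shrink it for small frames |
| `n_epoch` | 40 | optimization epochs per frame; convergence is typically reached well before, late epochs fine-tune at the decayed learning rate |
| `lr` | 1 px | Adam step scale; linear decay to `lr_decay_floor` (0.1) leaves final adjustments sub-pixel |
| `lr_floor`, `lr_ceil` | 0.3, 1.5 | learning-rate multipliers for the most/least similar parent–child pairs |
| `blur_start`, `blur_stages` | 2 px, 4 | coarse-to-fine foveation: descriptor blur decays linearly over equal epoch blocks from 2 px to 0 (the final block always runs at native resolution) |
| `fovea_sigma` | 6 px | Gaussian weighting of the descriptor correlation toward its center, so the keypoint itself outweighs neighbors inside the patch while context still contributes; `NULL` gives the plain unweighted correlation |
| `j_neighbors` | 5 | spring edges per keypoint |
| $\lambda_R, \lambda_N, \lambda_D, \lambda_T$ | 1, 0.1, 0.1, 0 | $L_N$ is measured in relative edge-length units and dominates if weighted equally with $L_R$ on strongly deforming scenes; 0.1 balances the two at this scale. $L_T$ is off by default because it presumes registered neighbors |
| `epsilon` | 2 frames | temporal patch half-width |
| `target_sigma` | 2 px | width of the Gaussian bumps forming the detector-training target |
| `pos_weight` | 2 | positive-class weight in the combiner's cross-entropy; features occupy well under 1% of the voxels, so unweighted training leaves the map under-confident everywhere, while full class balancing saturates it and litters frames of unseen postures with spurious peaks |

Two deliberate deviations from the most literal reading of the loss are
worth flagging. First, the tracked registration term applies the foveal
center-weighting above; the exported `loss_registration()` is the plain
unweighted formula, and setting `fovea_sigma = NULL` makes the tracker use
exactly that. Second, the Adam update is normalized per keypoint rather than per
coordinate: the second moment tracks each keypoint's squared gradient
*norm*, so the step direction follows the actual gradient and an axis
whose gradient sits at floating-point noise level (the z axis of a
perfectly centered blob, say) receives a proportionally tiny step instead
of the full learning-rate step coordinate-wise Adam would take in the
noise direction. Keypoints whose whole gradient norm falls below
$10^{-6}$ are treated as converged and frozen for that epoch.

## The synthetic study system

Every quantitative claim in the test suite is computed on movies from
`generate_movie()`. The `worm3d` preset emulates a head-ganglion-like
scene: 60 keypoints on a smooth backbone curve with transverse jitter in a
16×128×128 volume, a traveling-wave bending deformation plus slow global
rotation, drift, and a low-order polynomial field (so neighboring
keypoints move coherently), blob rendering as anisotropic Gaussians
(σ = 1.5 px in-plane) with additive Gaussian noise (σ = 0.03) and 16-bit
quantization, and a hard cap of 4 px on any keypoint's frame-to-frame
displacement. The bending amplitude (5 px) is set so that total
displacement relative to the internal body frame is a few nucleus
diameters, matching the relative-motion scale reported for freely crawling
nematodes once frames are rescaled; blob centers are kept at least ~3 px
apart because nuclei do not interpenetrate. The `posture2d` preset instead
cycles deterministically through three discrete postures to exercise
similarity sorting and reference recommendation. With two channels,
channel 2 carries stable blob intensities and channel 1 is modulated by
slow per-keypoint sinusoidal activity under a double-exponential
photobleach decay, which is what the trace-extraction recovery test
reconstructs.

What the generator does *not* emulate: optical point-spread anisotropy
beyond the blob covariance, depth-dependent attenuation, camera artifacts,
occlusion, and keypoints entering or leaving the volume. Passing the
synthetic benchmark therefore demonstrates that the optimization machinery
is correct and well-conditioned at realistic geometry, noise, and motion
scales — not that any particular accuracy will be reached on a given real
recording, where descriptor quality and posture coverage by the chosen
references dominate.

## Numerical choices and degenerate inputs

* Coordinates are normalized to $[-1, 1]$ per axis with align-corners
  endpoints; an axis of size 1 (2D video) has coordinate identically 0 and
  zero gradient. Internally all optimization happens in pixel units so
  steps are isotropic in physical space.
* Pearson correlations define zero-variance operands as correlation 0
  (distance 1 in the similarity matrix, term 1 in $L_R$) with zero
  gradient — a keypoint over a blank region contributes no registration
  force and is carried by its springs.
* The descriptor blur uses truncated (3σ), per-position renormalized
  Gaussian kernels; its exact adjoint is used in backpropagation, which is
  what makes finite-difference gradient checks pass at $10^{-4}$ relative
  error.
* Rest lengths are computed with the same vector-norm expression the
  spring loss uses, so a configuration identical to its reference scores
  exactly zero (down to the last ulp) and produces no spurious |·|
  subgradients.
* Out-of-frame descriptor samples clamp to the border value by default
  (`pad_policy = "zero"` is available); tracked coordinates may drift
  slightly outside $[-1,1]$ and the annotation validator tolerates an
  overshoot of 0.1.
* Ties are broken deterministically everywhere (lowest frame index in
  k-medoids and branch growth; `order()` index order in nearest-neighbor
  search), and every stochastic component takes an explicit seed, so a
  tracking run is exactly reproducible.
* k-medoids swaps only accept strict improvements (> $10^{-15}$), which
  guarantees termination and a non-increasing score trace.

## Limitations

* At least one fully annotated reference frame is required, and every
  worldline must be annotated in each reference.
* Identity swaps between near-identical adjacent blobs remain the dominant
  failure mode, as for any correlation-based matcher; the spring and
  detection terms reduce but do not eliminate them, and the package's
  intended workflow is the same as the field's: inspect, pin a few
  corrections, re-run (corrections cascade to child frames).
* The temporal term assumes intensity changes slowly relative to the frame
  rate; for fast reporters it should stay disabled.
* HDF5 container support is not compiled in; videos travel as multi-page
  TIFF or in-memory arrays, annotations as CSV.
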