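---
title: "Super-resolving motion-corrected model-based reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolving motion-corrected model-based reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(supermoco)
```

## The reconstruction problem

Free-breathing 3D whole-heart cardiac MR trades resolution against scan
time. This package reconstructs a high-resolution complex volume
$\rho \in \mathbb{C}^N$ of the heart at end-expiration from a short scan
that is *low-resolution* (only the center of the $k_y$–$k_z$ plane is
acquired) and possibly *undersampled* (only a variable-density subset of
the remaining lines is visited), while every heartbeat of data is used
regardless of respiratory position.

The acquisition is modeled by a linear encoding operator

$$ b = E\rho, \qquad E = W\,D\,F\,C\,M , $$

where $M$ warps the reference image into each of $N_b$ respiratory bins
with dense non-rigid displacement fields, $C$ multiplies by $N_c$
normalized coil sensitivity maps, $F$ is the centered *unitary* 3D Fourier
transform, $D$ selects the acquired $(k_y,k_z)$ readout lines — removing
both undersampled-away lines and everything outside the low-resolution
shutter — and the diagonal $W$ holds soft-gating weights in $[0,1]$.
Because the readout direction $x$ is always fully sampled, artifacts
propagate only in the $y$–$z$ plane, and volumes can be processed in
overlapping readout-direction patches.

The zero-filled bin images $\rho_{ZF} = C^* F^{-1} D^T W^T b$ are the only
data the iterative reconstruction needs: the identity
$E^*b = M^*\rho_{ZF}$ lets the data-consistency step run from images
rather than raw samples.

## The unrolled ADMM iteration

Reconstruction solves

$$ \min_{\rho,\omega}\ \tfrac12\|E\rho-b\|_2^2
   + \tfrac{\mu}{2}\|\omega - S(\omega)\|_2^2
   \quad \text{s.t. } \rho=\omega , $$

where $S$ is a learned super-resolving denoiser assumed (and trained) to
act as a projector onto the set of clean high-resolution images. The
scaled-ADMM steps are

1. $\rho^{j+1} = \arg\min_\rho \tfrac12\|E\rho-b\|^2 +
   \tfrac{\lambda}{2}\|\rho-\omega^j+a^j\|^2$, solved by a fixed number of
   conjugate-gradient iterations initialized at $\omega^j - a^j$;
2. $\omega^{j+1} = \frac{\mu}{\mu+\lambda}S(\tilde\omega^j) +
   \frac{\lambda}{\mu+\lambda}\tilde\omega^j$ with
   $\tilde\omega^j = \rho^{j+1}+a^j$ — the closed-form minimizer of Step 2
   under the projector assumption (a convex combination: the coefficients
   are nonnegative and sum to one);
3. $a^{j+1} = a^j + \rho^{j+1} - \omega^{j+1}$, the conventional scaled
   dual update (the residual accumulation is the only sign choice that
   drives $\rho = \omega$).

The final iteration stops after Step 1, so the returned image is the last
data-consistent solve. The initial image is the motion-corrected adjoint
$\rho^0 = \sum_b M_b^*\rho_{ZF,b}$ — of the reasonable initializations
(zero-filled, adjoint, SENSE) the adjoint is the natural data-derived
choice and is consistent with the $E^*b$ identity.

Defaults follow the framework's reference operating point: $\lambda = 1.5$,
$\mu = 10$, 4 ADMM iterations, 5 CG iterations per Step 1, 10 iterative
SENSE iterations for the auxiliary images, 4 respiratory bins. CG uses a
fixed iteration count with no early exit so the unrolled computation has
a fixed depth during training.

## Motion model

Respiratory motion is handled twice:

* **Translational correction**: per-heartbeat in-plane (foot–head $x$,
  left–right $y$) displacements are estimated from 2D coronal image
  navigators by normalized cross-correlation over integer shifts with
  parabolic sub-pixel refinement — the simplest robust choice for
  low-resolution navigator registration. The
  correction is the k-space phase ramp
  $\exp(-2\pi i(k_x d_x/N_x + k_y d_y/N_y))$, which is exactly unitary.
* **Non-rigid fields**: each bin's zero-filled image is de-noised by a few
  iterations of single-bin iterative SENSE (with a small Tikhonov term
  $\epsilon = 10^{-6}$, since undersampled single-coil bins are
  rank-deficient), and pairs (reference, bin) of magnitude images are fed
  to a 3-level 3D U-Net that outputs a stationary velocity field. A
  scaling-and-squaring layer (default 6 steps, trilinear self-composition,
  clamped boundary sampling) exponentiates the velocity, so the output
  displacement has positive Jacobian determinant — diffeomorphic by
  construction, for any network weights. The warp adjoint used inside
  $E^*$ is the exact transpose of the trilinear interpolation matrix
  (a scatter of the interpolation weights), not an inverse-warp
  approximation, so operator adjoint tests pass at numerical precision.

Fields map reference-bin coordinates into each bin ($M$ warps the
reference image into bin $i$); the inverse maps needed by the motion loss
are obtained as $\exp(-v)$.

The network consumes magnitude images only: registration is
contrast-driven and the complex phase carries no additional alignment
information at this scale. Inputs are zero-padded to pooling-compatible
sizes and internally downsampled by 2; output velocities are upsampled
(displacements scaled by 2) and cropped back. At full scale this
corresponds to registering padded $32\times304\times128$ patches; at desk
scale the pad target adapts to the input geometry with the same
mechanism.

## Learned components and training

Both networks are 3-level 3D U-Nets (two 3×3×3 convolution + ReLU blocks
per level, average-pool downsampling, nearest-neighbour upsampling with
skip concatenation) with hand-written forward and backward passes; Adam
is the optimizer throughout. The super-resolving denoiser is residual
($S(x) = x + \mathrm{UNet}(x)$) on the 2-channel real/imaginary
representation; its near-idempotence is a property approached by
training, not an axiom, and is checked statistically in the tests.
Channel widths are configurable and treated as a free parameter
(desk-scale experiments use 4–16 channels).

**Perceptual loss.** Image quality is trained with a weighted sum of mean
squared errors on five feature maps, with readout-direction slices as the
2D batch:
$L_{perc} = \sum_{\nu=1}^{5}\psi_{c_\nu,d_\nu}L_{feat,c_\nu,d_\nu}$, with
the reference weights $\psi_{1,1}=3.0$, $\psi_{2,2}=0.04$,
$\psi_{3,3}=0.016$, $\psi_{4,3}=0.01$, $\psi_{5,4}=14.0$. The feature
extractor is pluggable: the conventional pretrained 2D feature network
can be supplied where its weights are available locally; the package
default (and the test suite) uses a frozen random convolutional extractor
with the same five tap points, so everything runs offline and
deterministically. Feature-map normalization averages over batch, width,
height and channels (averaging over channels, rather than summing, is the
convention adopted here).

**Pre-training** minimizes
$L_{pretrain} = \gamma_1 L_{perc} + \gamma_2 L_{SRreg}$ with
$\gamma_1 = 100$, $\gamma_2 = 1$ on paired low/high-resolution volumes
produced by retrospective down-sampling; default learning rate
$10^{-5}$. $L_{SRreg}$ is implemented as the sum of squared convolution
kernel entries — standard weight decay; the squared norm is chosen over
the plain norm for its simpler gradient.

**End-to-end training** minimizes
$L = \eta_1 L_{perc} + \eta_2 L_{reg} + \eta_3 L_{mot}$ with
$\eta_1 = 10$, $\eta_2 = 1$, $\eta_3 = 100$; default initial learning
rate $10^{-4}$, halved after 500 epochs. $L_{mot}$ is the self-supervised
Charbonnier loss $\mathrm{mean}\sqrt{|x-y|^2+\varepsilon^2}$
($\varepsilon = 10^{-3}$) between the high-resolution reference image and
the other bins warped to the reference with $\exp(-v)$; no ground-truth
motion is ever used. Gradients reach the denoiser through the unrolled
ADMM: the vector–Jacobian product of the fixed-depth CG solve is
approximated by another CG solve with the same normal matrix (the
standard unrolled-model-based trick; the dependence of the solve on its
initialization is neglected). Motion fields are treated as constants
inside the data-consistency backward pass; the motion network receives
its gradients from $L_{mot}$ through the warp and scaling-and-squaring
layers, whose vector–Jacobian products are exact.

Three pragmatic aids are available in `train_motion_net()` (none is used
in the end-to-end loss): a coarse-to-fine pyramid variant of the
Charbonnier loss (average-pooled terms), minibatch gradient
accumulation, and a diffusion (squared forward-difference) smoothness
prior on the predicted velocity. The smoothness prior is essential, not
cosmetic: an intensity loss only constrains the displacement where the
image has gradients (the aperture problem), so without it the network
happily matches edges with spatially incoherent fields whose mean
displacement says nothing about the true motion. Both the pyramid and
the diffusion regularizer are standard components of the registration
network family this motion branch belongs to.

## Training-pair generation

Low-resolution training inputs are produced by *retrospective
down-sampling* of acquired data, never by synthesizing samples: the
density profile of a prospective-style low-resolution mask is measured
over 20 concentric elliptic annuli (equal width in normalized elliptical
radius), the annuli are scaled onto the high-resolution grid by the SR
factor, everything outside the outermost annulus is discarded, and within
each annulus acquired lines are randomly retained until the measured
density is matched (if an annulus cannot reach its target the shortfall is
recorded and all available lines are kept). Retained values bit-match the
source data. k-space is zero-padded in $k_y$/$k_z$ to the next multiple
of 16 so pooling layers never meet odd sizes; under the unitary DFT
convention the padded samples are rescaled so image amplitudes are
preserved.

## Patching

Volumes are split along $x$ into patches of thickness 32 (a multiple of
16), a five-voxel edge layer is discarded on interior sides after
processing, and adjacent retained intervals overlap by four voxels
(stride 18), the overlaps being averaged on recombination. The first and
last patches keep their outer edge voxels. Patch starts advance at the
regular stride with the final patch anchored at the end of the axis; when
the leftover gap is smaller than the overlap the preceding regular start
is dropped, which guarantees no voxel is covered by more than two
retained intervals — overlap averaging is then exact in floating point,
and the identity-processing round trip reproduces the input bit for bit.

## The synthetic phantom

Every stage is testable without any download through a synthetic moving
phantom:

* **Anatomy**: analytic soft-edged ellipsoids (torso plus chamber-like
  blobs) and one curved bright tube of about 2 voxels diameter for vessel
  sharpness evaluation. Edge widths are about 1.5 voxels, and a
  band-limited random texture (15–45% of the Nyquist radius, ~20%
  modulation) stands in for trabeculation and other fine structure — so
  the phantom carries genuine spatial-frequency content beyond the
  low-resolution shutter, as real whole-heart angiography does. A
  visibly smooth phantom would make super-resolution trivially lossless
  and any comparison of acquisition schemes meaningless. A smooth random
  phase field makes the volume genuinely complex.
* **Breathing**: a pseudo-periodic sum of two incommensurate sinusoids
  (periods ≈ 4.3 and 13.7 heartbeats) with seeded jitter; foot–head
  amplitude equals `motion_amplitude_vox` (default 3 voxels), left–right
  0.4 of that.
* **Motion**: each bin's true field is a bulk in-plane translation (the
  bin's mean breathing displacement) plus a low-spatial-frequency
  non-rigid component built by scaling-and-squaring of a smooth random
  velocity scaled with the bin's foot–head offset — so ground-truth
  deformations are diffeomorphic by construction and the bin-image
  invariant `warp(reference, field_i) == bin_i` holds exactly.
* **Acquisition**: per heartbeat, readouts sample the k-space of that
  heartbeat's non-rigid bin state, with the full continuous per-heartbeat
  translation applied as a phase ramp — so the downstream translational
  correction has real work to do. iNAVs are central-slab coronal
  magnitude projections at 2× coarser resolution, shifted with the
  breathing position. Noise is i.i.d. complex Gaussian per sample with
  SNR defined as mean |signal| divided by the complex noise standard
  deviation.
* **Trajectory**: variable-density Cartesian sampling in an elliptical
  shutter with spiral-arm interleaves rotated by the golden angle
  (≈111.25°) per heartbeat and density decreasing with elliptical radius;
  no canonical formula exists for the interleave construction, so the
  generator documents its own: exact-count
  weighted sampling (weight $\propto (1-r+0.05)^2$) followed by
  nearest-arm assignment with per-heartbeat capacity, ordered center-out.
* **Soft gating**: heartbeats are hard-assigned to equally populated
  foot–head quantile bins (ties by heartbeat order); neighboring bins
  receive Gaussian weights $\exp(-d^2/2\sigma^2)$ with $\sigma$ half the
  bin's quantile width, truncated to zero below 0.05, weight 1 in the
  assigned bin. The reference bin is the one with smallest mean
  displacement (end-expiration). The cited soft-gating references state
  no formula; the Gaussian form is the community convention.

What the phantom does **not** emulate: steady-state contrast physics,
cardiac (intra-beat) motion, eddy currents, off-resonance, coil coupling,
or realistic anatomy texture. Passing tests therefore demonstrate the
correctness of the operators, the training machinery and the end-to-end
plumbing under known ground truth — not clinical image quality.

## Evaluation metrics

* **Scale-optimized ROI MSE**: the reference magnitude is normalized to a
  ROI maximum of 1; the reconstruction scale is the closed-form
  least-squares factor, making the metric invariant to global complex
  scaling.
* **Scale-optimized ROI SSIM**: uniform 7-voxel window, standard
  constants, computed on the ROI bounding box; the scale is found by
  golden-section search over $[0.1, 10]$ — the common SSIM defaults. The scale is optimized per
  metric, reading "scaled separately to optimize the metrics" literally.
* **Vessel sharpness**: for centerline points within the first 4 cm,
  intensity profiles perpendicular to the local vessel direction are
  sampled on both sides; per side, sharpness is $\min(1, 1/d_{20-80})$
  with $d_{20-80}$ the distance between the 20% and 80% crossings of the
  local (max − background) range, background being the 10th percentile of
  the profile; sides without an edge score 0; the mean is reported in
  percent. The 0% and 100% anchors (no edge; transition within one
  sample) define the scale; the inverse-edge-distance convention follows
  the established coronary sharpness tools, and the score is capped at
  100%.
* **Paired tests**: paired t or Wilcoxon signed-rank with a Bonferroni
  threshold $0.05/n$ (≈0.0033 at 15 comparisons, ≈0.0083 at 6).

## Problem sizes used by the test suite

The suite runs everything at desk scale, chosen so the whole battery of
operator, property and learning checks completes comfortably on one CPU:
operator and dense-oracle tests on $4^3$–$16^3$ grids; diffeomorphism
checks on $32^3$; motion-recovery training on $12\times24\times12$
volumes with breathing-like translations (foot–head up to ±3 voxels);
end-to-end training on 8 synthetic subjects with $16\times64\times32$
grids, 2 coils, 4 bins, 48 heartbeats, SNR 30, and the two acquisition
schemes (4×4 SR at ≈1.15× undersampling; 2×2 SR at 4.5×) whose overall
acceleration is matched at ≈18×; five subjects train the networks and
the reported MSEs average the three held-out subjects. Networks use
2–16 channels in these experiments. These sizes are the package's
own desk-scale study conditions; clinical-scale training and evaluation
are orders of magnitude larger in every dimension.

## Known limitations

* The CG gradient is the approximate solve-based VJP; exactness would
  require differentiating the CG recurrence itself.
* The motion network is trained at desk scale only; quantitative motion
  recovery is demonstrated for translation-dominated deformations.
* The feature extractor default is a frozen random network; the
  perceptual weights were calibrated against a pretrained extractor, so
  their relative calibration is only qualitatively meaningful here.
* Non-Cartesian encoding, coil-map estimation, bulk-motion rejection and
  multi-contrast reconstruction are out of scope.
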