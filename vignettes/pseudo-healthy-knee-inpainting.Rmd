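---
title: "Pseudo-healthy knee MRI by wavelet-domain diffusion inpainting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-healthy knee MRI by wavelet-domain diffusion inpainting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoknee)
```

## The problem

Trochlear dysplasia (TD) is a malformation of the femoral trochlea — the
groove on the anterior distal femur in which the patella glides. On an axial
MR slice it shows as an abnormally large **sulcus angle** (SA, the angle at
the deepest sulcus point between lines to the highest medial and lateral
condyle points) and a reduced **trochlear groove depth** (TGD, the anterior
distance from the condylar apex level to the sulcus nadir). Surgeons
correcting the groove lack a patient-specific target shape. This package
synthesises one: it masks the (potentially pathological) region around the
patella and *inpaints* it with plausible healthy anatomy that is conditioned
on the patient's own unmasked tissue — in particular their patella — yielding
a *pseudo-healthy* volume of the same knee.

## Pipeline overview

1. **Preprocessing** (`preprocess_volume()`): resample to 0.6 × 0.6 × 4.5 mm,
   center-crop then zero-pad to 256 × 256 × 32 voxels, clip the 1st/99th
   intensity percentiles and rescale to [0, 1]. These values match the axial
   proton-density fat-saturated protocols the model targets.
2. **Masking** (`mask_pathology()`): Otsu thresholding + morphology +
   largest-component extraction segments the background, which is zeroed
   (`y0`). Bone is segmented by a pluggable backend; the patella is the
   largest bone component with an anterior centroid; the inpainting mask `m2`
   is a "bowl" of all voxels within 30 mm (Euclidean, in mm, honouring the
   anisotropic spacing) of the patella, excluding the patella itself and
   clipped to the foreground. An analytic ellipsoid replaces the bowl when no
   patella is found.
3. **Wavelet transform** (`dwt3()`/`idwt3()`): a single-level orthonormal 3D
   Haar decomposition into 8 half-resolution subbands `lll … hhh`.
4. **Conditional diffusion** (`diffusion` + `denoiser` + `train` modules): a
   DDPM in wavelet space whose network input concatenates the noisy
   coefficients `x_t` with the wavelet transforms of the masked image `m1`
   and mask `m2` (24 channels), predicting the clean coefficients `x0`
   directly.
5. **Evaluation** (`masked_mse()`, `masked_psnr()`, `masked_ssim()`,
   `sulcus_angle()`, `trochlear_groove_depth()`,
   `detect_trochlea_landmarks()`): masked image-quality scores and automated
   trochlear morphometry.

## The diffusion model

The forward process corrupts clean wavelet coefficients with the closed-form
marginal \(x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon\),
where \(\alpha_t = 1-\beta_t\), \(\bar\alpha_t = \prod_{s\le t}\alpha_s\) and
\(\beta_1,\dots,\beta_T\) is a linear schedule (defaults \(10^{-4}\) to
\(0.02\), \(T = 1000\); `make_linear_schedule()`). With those defaults
\(\bar\alpha_T \approx 4\times10^{-5}\), so the terminal marginal is
effectively a standard Gaussian.

The network is an \(x_0\)-predictor: given \(X_t = (x_t, \mathrm{DWT}(m_1),
\mathrm{DWT}(m_2))\) and \(t\) it outputs \(\tilde x_0\). Sampling uses the
DDPM posterior

\[
\mu_t = \frac{\sqrt{\bar\alpha_{t-1}}\,\beta_t}{1-\bar\alpha_t}\tilde x_0
      + \frac{\sqrt{\alpha_t}\,(1-\bar\alpha_{t-1})}{1-\bar\alpha_t}x_t,
\qquad
\tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t,
\]

with \(\bar\alpha_0 := 1\), so that \(\tilde\beta_1 = 0\) and the chain ends
deterministically at \(\tilde x_0\). Wavelet coefficients are not
range-bounded, so no clamping happens inside the chain; only the final image
is clamped to [0, 1] after the inverse transform. The output is composited as
`m2 * inpainted + (1 - m2) * original`, so voxels outside the mask are
returned bit-identical — the patient's own anatomy, including the patella the
synthesis is conditioned on, is never altered.

The training loss is the mean squared error between \(\tilde x_0\) and
\(x_0\) over all 8 subbands plus an L1 sparsity penalty (weight
`lambda_reg`, default 1) on the *predicted* `hhh`, `hhl`, `hlh` and `lhh`
subbands — the bands combining x/y high-pass filters, where edge noise
concentrates. `llh`, `lhl` and `hll` are not regularized. Only the prediction
enters the penalty because the ground-truth bands are constant with respect
to the model.

### Why orthonormal Haar

The reference formulation leaves the wavelet normalization open (any fixed
global scale admits perfect reconstruction). This package uses the
orthonormal convention (filters \((1,\pm1)/\sqrt2\)): the transform then
preserves energy exactly (Parseval), so unit-variance white noise in image
space stays unit-variance white in wavelet space and the diffusion marginals
in the two domains agree without correction factors. A constant volume `c`
maps to an `lll` subband constant at \(2\sqrt2\,c\).

## The denoiser network

`denoiser_config()` describes a 3D U-Net over wavelet coefficients: residual
blocks with group normalization and SiLU, a sinusoidal time embedding passed
through a two-layer MLP and injected per block as a channel bias, up/down
sampling inside dedicated residual blocks (average pooling / nearest
neighbour), additive encoder-to-decoder skip connections, single-head
self-attention at the bottleneck, and zero-initialized output projections (an
untrained network predicts exactly 0). The full-scale configuration — 64 base
channels, channel multipliers (1, 2, 2, 4, 4), 2 residual blocks per scale,
24 → 8 channels — has **57,954,120** trainable parameters, within 0.02 % of
the 57.94 M reported for the architecture family this design follows; the
exact internal layout of that reference implementation (attention placement
and embedding widths) is not fully specified in print, so the remaining
difference cannot be attributed. `count_denoiser_params()` is a pure function
of the configuration and is cross-checked in the test-suite against an
independent layer-by-layer summation.

Because no deep-learning framework is available to R in this environment,
the layers and their backward passes are implemented in the package itself
(im2col-based 3D convolution in C++ with BLAS matrix products, hand-derived
gradients for group norm, attention, pooling and the residual topology) and
validated against central finite differences in the test-suite.

## The synthetic phantom

`generate_phantom()` builds a stylised axial knee with known ground truth: a
femur-like slab whose anterior surface carries two condylar ridges separated
by a V-shaped groove, an ellipsoidal patella anterior to the groove, a smooth
soft-tissue envelope, and background. Intensities are piecewise constant per
tissue class (defaults: background 0.05, soft tissue 0.4, bone 0.9), blurred
in-plane (Gaussian, 1.2 voxels) and degraded with additive Gaussian noise
(default sd 0.02 — a compromise between a visibly noisy acquisition and
keeping the three-class histogram separable, matching what the masking stage
assumes of normalized PD fat-saturated data).

Geometry is analytic: with groove depth \(g\) (= TGD) and sulcus angle
\(\theta\), the condyle apices sit \(d = g\tan(\theta/2)\) either side of the
nadir. This coupling means not every (SA, TGD) pair fits a knee-sized volume
— e.g. SA 170° with TGD 6 mm would need condyles 69 mm apart — so validation
rejects such specs, and the recovery tests pair SA ∈ {130°, 150°} with TGD ∈
{3, 6} mm, SA 170° with TGD 1.8 mm, and TGD 0 (flat trochlea, SA 180° by
construction). The apex line and the one-voxel-wide apex/nadir flats are
snapped to the voxel grid so the voxelised surface realizes the requested
geometry without sub-voxel bias; recovery through the full automated chain
(surface profile → plateau-aware local maxima → angle/depth) is within
2°/0.3 mm, and exact from the ground-truth landmark table.

`generate_pathological_phantom()` emulates TD by filling the groove: the
nadir rises toward the apex line while the condyles stay fixed, so measured
SA increases monotonically with the fill fraction and TGD reaches 0 at full
fill.

What the phantom does *not* emulate: MR physics (coils, bias fields, fat
saturation), anatomical variability of real knees, cartilage/bone contrast
inversions, or patella dislocation. Passing tests therefore demonstrate
correctness of the algorithms under controlled geometry, not clinical
performance.

## Numerical and design choices

- **Otsu threshold**: fixed 256-bin histogram on [0, 1]; between empty bins
  all boundaries tie exactly, so the threshold is the middle of the optimal
  plateau (the convention that places the threshold midway between separated
  modes). Equality with an exhaustive brute-force maximizer is asserted in
  the tests.
- **Morphology in millimetres**: opening 1.8 mm / closing 2.4 mm spherical
  elements, realised through an exact anisotropic Euclidean distance
  transform (separable lower-envelope algorithm) rather than voxel-count
  dilation, because 30 mm at 0.6 × 0.6 × 4.5 mm spacing is 50 in-plane voxels
  but only ~6.7 slices.
- **Connectivity**: 26-connectivity for all 3D component labelling.
- **"Anterior region"** for patella search: the anterior 40 % of the y
  extent (configurable); in axial knee MRI the patella is the anterior-most
  bone.
- **Resampling**: trilinear for images, nearest for masks; voxel centres at
  `index * spacing` with edge clamping. Percentile clipping is computed over
  the whole volume (the background is included; with 1/99 defaults this is
  insensitive to the choice).
- **Masked SSIM**: both volumes are zeroed outside the mask, a dense SSIM map
  (7³ Gaussian window, σ 1.5, data range 1, symmetric padding) is computed
  over the whole volume, and map values are averaged at mask voxels. Windows
  straddling the mask boundary see the shared zero silhouette, which biases
  the score upward for thin masks — a property of this construction worth
  keeping in mind when comparing absolute values across mask shapes.
- **TGD aggregation**: the mean of the two condyle apex heights (the plural
  "highest points" admits mean or max; `method = "max"` is available).
- **Training details**: Adam (the optimizer is not prescribed by the
  formulation; Adam is the field default), x0-prediction target, uniform
  time-step sampling, masks supplied per volume or by a sampling policy
  function. The `"full"` profile records full-scale practice (lr 1e-5,
  batch 10, 1e6 iterations, T = 1000); the `"desk"` profile used by the
  test-suite overfits one 16 × 16 × 8 phantom with the tiny configuration
  (8 base channels, multipliers (1, 2), 87,808 parameters), T = 100, lr
  2e-3, batch 1, 2000 iterations — sized so the whole suite runs on one CPU
  in minutes. At that scale training reduces the loss to about 1 % of its
  initial value and inpaints the masked groove to a masked MSE ≈ 0.004.
- **Desk-scale bowl**: at 2.4 mm in-plane spacing the bowl offset is 8 mm —
  scaled so the mask reaches the sulcus nadir, as the 30 mm bowl does at full
  scale.

## The desk-scale restoration experiment

The clinical claim of the method — inpainting moves dysplastic morphometry
toward healthy values — has a desk-scale analogue that the acceptance script
recomputes end to end: a tiny model is overfit to one healthy phantom
(SA 130°, TGD 3 mm); a 90 %-filled version of the same phantom (measured at
desk resolution: SA 180°, TGD 0 mm) is masked and inpainted; the inpainted
volume's measured SA falls back to within a few degrees of the healthy
phantom's desk-scale value (≈ 140°) and its TGD recovers. Direction, not
magnitude, is the tested contract: the single-phantom overfit regime says
nothing about generalisation across anatomies.

## Known limitations

- The network trains on CPU in R; full-scale (256 × 256 × 32, 58 M
  parameters, 10⁶ iterations) training is out of reach here — the full-scale
  configuration is constructed and counted, never trained.
- The DICOM reader supports uncompressed little-endian single-frame series
  only (sufficient for the targeted axial MR exports); compressed transfer
  syntaxes need conversion to NIfTI first.
- Landmark detection assumes the axial slice shows both condyles with
  near-equal apex heights, as phantom geometry guarantees; surgeon-grade
  landmarking of clinical MRI is out of scope.
- The bundled `"threshold"` bone backend suits bright-bone contrast
  (phantoms); real knee MRI should use an external segmentation through the
  `"file"` backend or a registered custom backend.
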