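# pseudoknee

Patient-specific **pseudo-healthy 3D knee MRI** by conditional wavelet-domain
diffusion inpainting, with automatic pathology masking around the patella and
quantitative trochlear morphometry.

## The problem

Trochlear dysplasia (TD) is a malformation of the femoral trochlea — the
groove in which the patella glides — that causes patellar maltracking and
instability in adolescents. Corrective surgery (trochleoplasty) reshapes the
groove, but there is no standardized patient-specific target shape. This
package generates one: it masks the region around the patella in an axial
knee MR volume and replaces it with plausible *healthy* anatomy synthesized
by a diffusion model conditioned on the patient's own unmasked tissue,
including their patella. On the synthetic output, clinically used TD metrics
— the **sulcus angle** (SA, angle at the sulcus nadir between rays to the two
condylar apices; larger = shallower = worse) and the **trochlear groove
depth** (TGD) — move toward healthy values.

## Method in brief

- **Preprocess**: resample to 0.6 × 0.6 × 4.5 mm, center-crop/pad to
  256 × 256 × 32, percentile-clip and normalize to [0, 1].
- **Mask**: Otsu + morphology + largest-component background removal; bone
  segmentation (pluggable backend); patella = largest bone component with an
  anterior centroid; inpainting mask `m2` = 30 mm "bowl" around the patella
  (exact anisotropic Euclidean distances), patella excluded, with an analytic
  ellipsoid fallback.
- **Model**: single-level orthonormal 3D Haar DWT into 8 subbands; a DDPM
  (linear β schedule, T = 1000) in wavelet space whose 3D U-Net takes
  `(x_t, DWT(m1), DWT(m2))` (24 channels) and predicts the clean
  coefficients x0; loss = MSE + L1 sparsity on the predicted `hhh`, `hhl`,
  `hlh`, `lhh` subbands; reverse sampling via the DDPM posterior
  `μ_t = √ᾱ_{t-1} β_t/(1-ᾱ_t) · x̃0 + √α_t (1-ᾱ_{t-1})/(1-ᾱ_t) · x_t`,
  `β̃_t = (1-ᾱ_{t-1})/(1-ᾱ_t) · β_t`. The final volume is composited so
  voxels outside `m2` are bit-identical to the input.
- **Evaluate**: masked MSE / PSNR / SSIM (SSIM: zero outside the mask, dense
  map, average over mask voxels) and automated SA / TGD from the anterior
  bone-surface profile.

All network layers (3D convolution, group norm, attention, time embedding)
and their gradients are implemented in the package (Rcpp + BLAS); a built-in
phantom generator provides knees with analytically known groove geometry so
every stage is testable without any external data.

## Worked example

```r
library(pseudoknee)

# a synthetic knee with a 150° sulcus angle and a 5 mm groove
ph <- generate_phantom(phantom_spec(sulcus_angle_deg = 150, groove_depth_mm = 5, seed = 42))
ph$volume
#> <volume_image> 112x112x16 voxels, spacing (0.6, 0.6, 4.5) mm, range [0, 0.9815]

# background removal, bone segmentation, patella localization, bowl mask
mp <- mask_pathology(ph$volume)
mp$m2
#> <binary_mask> 112x112x16 voxels, spacing (0.6, 0.6, 4.5) mm, 66476 foreground

# automated trochlear morphometry on the central slice
det <- detect_trochlea_landmarks(ph$volume, mp$bone, ph$central_slice, mp$patella)
sulcus_angle(det)            # 149.8  (constructed: 150°)
trochlear_groove_depth(det)  # 5.10   (constructed: 5 mm)
```

The measured SA of 149.8° and TGD of 5.10 mm recover the constructed
geometry through the full segmentation + landmark pipeline on a noisy
phantom.

Training and inference at desk scale (a tiny model overfit to one
16 × 16 × 8 phantom; minutes on one CPU):

```r
d   <- list(vol = ..., m2 = ...)                     # preprocessed volume + mask
ck  <- train_denoiser(list(d$vol), list(d$m2), train_config("desk", seed = 7))
out <- infer_pseudo_healthy(ck, d$vol, mask = d$m2, seed = 11)
masked_mse(d$vol, out$volume, d$m2)                  # ~0.004 at convergence
```

A command-line front end covering the same steps ships in
`inst/cli/pseudoknee` (`phantom`, `preprocess`, `mask`, `dwt`, `train`,
`infer`, `evaluate`, `morphometry`, `model-info`).

## Package layout

| Module | Contents |
|---|---|
| `R/phantom.R` | synthetic knee phantoms with ground-truth geometry |
| `R/preprocess.R`, `R/dicom.R`, `R/volume.R` | NIfTI/DICOM I/O, resampling, crop/pad, normalization |
| `R/masking.R`, `R/morphology.R` | Otsu, EDT morphology, components, patella, bowl/ellipsoid masks |
| `R/wavelet.R` | orthonormal 3D Haar DWT/IDWT |
| `R/diffusion.R` | noise schedule, forward/reverse process, inpainting sampler |
| `R/nn.R`, `R/denoiser.R`, `src/ops.cpp` | autodiff tape, 3D U-Net, parameter counting |
| `R/train.R` | Adam training loop, checkpoints, inference |
| `R/metrics.R` | masked MSE/PSNR/SSIM, SA/TGD, landmark detection |
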