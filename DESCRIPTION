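Package: pseudoknee
Title: Pseudo-Healthy Knee MRI by Wavelet-Domain Diffusion Inpainting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates patient-specific pseudo-healthy 3D knee MR volumes for
    trochlear dysplasia assessment. Pathological tissue around the patella is
    masked automatically (Otsu background removal, bone segmentation, patella
    localization, a fixed physical-distance "bowl" mask) and re-synthesised by a
    conditional denoising diffusion model operating on the 8 subbands of a
    single-level 3D Haar wavelet decomposition. Includes volume preprocessing
    (resampling, center crop/pad, percentile normalization) for NIfTI and DICOM
    inputs, a synthetic knee phantom generator with known trochlear geometry,
    masked-region image-quality metrics (MSE, PSNR, SSIM) and automated
    trochlear morphometry (sulcus angle, trochlear groove depth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
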