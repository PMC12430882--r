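Package: specfusion
Title: Physics-Informed Spectral Reflectance Reconstruction from Paired RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-pixel spectral reflectance from a pair of RGB
    images -- an object image and a white-reference (light-source) image taken
    under the same illumination -- using a physics-informed fusion of two
    convolutional subnetworks: a U-Net-like spectral upsampling branch for the
    object radiance and an attention-based branch used twice, once to recover
    the illuminant spectrum and once to decode the channel-concatenated cubes
    into reflectance. Includes the discrete image-formation model (camera
    response projection, whiteboard illuminant measurement, wavelength-wise
    reflectance ratio), a synthetic spectral-scene simulator with parametric
    LED illuminants and tooth/ceramic-like reflectance fields, a composite
    structure-pixel (MSE + SSIM) training loss with brute-force oracles,
    per-band evaluation metrics, ablation variants, a plain U-Net baseline,
    and ENVI-style hyperspectral cube input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
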