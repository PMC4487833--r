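Package: dothisto
Title: Linking Diffuse Optical Physiology to Breast Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A verifiable analysis pipeline connecting macroscopic diffuse
    optical measurements of breast tumors (tumor-to-normal hemoglobin,
    oxygenation and scattering ratios from diffuse optical tomography,
    blood flow indices from diffuse correlation spectroscopy, and the
    derived relative mammary metabolic rate of oxygen) to microscopic
    histopathology biomarkers (Ki67 proliferation fraction, CD34 stained
    microvessel metrics, and nuclear compactness).  Includes a synthetic
    cohort generator that renders multi-wavelength absorption volumes,
    intensity autocorrelation scans and brightfield immunohistochemistry
    slides from known per-subject ground truth, so that every stage -
    chromophore unmixing, half-maximum tumor segmentation, correlation
    diffusion fitting, stain deconvolution, vessel and nuclear
    morphometry, and the small-sample correlation statistics - can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    RNifti,
    minpack.lm,
    mgcv,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
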