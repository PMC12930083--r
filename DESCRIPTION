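Package: perfstab
Title: Scan-to-Scan Stability Analysis of CT Perfusion Metrics with a Synthetic Dynamic Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the repeatability of CT perfusion (CTP) derived
    stroke metrics. Provides a digital dynamic-CTP phantom with known
    hemodynamic ground truth (gamma-variate arterial input, exponential tissue
    residues, configurable ischemic penumbra and core), a deconvolution-based
    perfusion engine (automatic arterial input function selection, regularized
    singular-value-decomposition deconvolution, CBF/CBV/MTT/Tmax maps with
    contralateral-free normalization to normally perfused tissue),
    threshold-based hypoperfusion and infarct-core volumetry (Tmax > 6 s,
    rCBF < 30 %), automated ASPECTS scoring on non-contrast CT via atlas
    region labels and inter-hemispheric Hounsfield-unit differences, and
    Bland-Altman / correlation agreement statistics across repeated scan
    pairs, including simulation of disruptive events and technical failure
    modes (bolus truncation, z-coverage shift, elevated noise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Rcpp,
    grDevices,
    jsonlite,
    pracma,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
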