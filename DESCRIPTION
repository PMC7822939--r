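Package: plaquemap
Title: Quantitative MRI Relaxometry and Tissue Classification for
    Atherosclerotic Plaque Phantoms
Version: 0.1.0
Authors@R:
    person("plaquemap", "developers", email = "plaquemap@example.org",
           role = c("aut", "cre"))
Description: Simulates tissue-labeled digital plaque phantoms and spoiled
    gradient-echo acquisitions at high field, estimates voxel-wise T1 maps by
    the linearized variable-flip-angle method and T2* maps by log-linear
    mono-exponential fitting, extracts region-of-interest feature vectors
    (mean/sd/min/max relaxation times and ROI size), and classifies plaque
    tissue components (fibrous tissue, lipids, inflammation, hemorrhage) with
    quadratic discriminant analysis, reporting per-plaque misclassification
    rates. Includes Fourier zero-filling interpolation, a minimal NIfTI-1
    reader/writer, YAML-configured end-to-end pipeline runs, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    truncnorm,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
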