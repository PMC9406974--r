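Package: perfstroke
Title: Perfusion Post-Processing and Thrombectomy Triage for Acute
    Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("perfstroke", "developers", email = "perfstroke@example.org",
           role = c("aut", "cre"))
Description: An automated post-processing pipeline for 4D perfusion
    imaging (CT perfusion and DSC-MRI) in acute ischemic stroke:
    preprocessing (motion correction, smoothing, brain masking),
    signal-to-concentration conversion, automatic arterial input
    function detection, delay-insensitive block-circulant
    truncated-SVD deconvolution, voxelwise rCBF/rCBV/MTT/Tmax maps,
    ischemic core and penumbra segmentation with configurable
    thresholds (rCBF < 30%, ADC < 620e-6 mm^2/s, Tmax > 6 s),
    DEFUSE3 mismatch-profile triage for mechanical thrombectomy, and
    method-agreement statistics (ICC(2,1) with confidence intervals,
    Bland-Altman limits of agreement, exact Wilcoxon signed-rank,
    triage concordance). Includes a digital perfusion phantom
    generator with known ground truth for end-to-end validation, a
    minimal NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
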