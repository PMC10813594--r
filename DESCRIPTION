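Package: csfflow
Title: Cine Phase-Contrast MRI Quantification of Pulsatile CSF Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulsatile cerebrospinal fluid (CSF) flow from
    cardiac-gated cine phase-contrast MRI. Builds a cardiac-fundamental
    parametric image by Fourier analysis of the per-pixel velocity time
    series, segments the pulsatile CSF region by thresholding, detects and
    corrects velocity aliasing against the velocity-encoding limit (VENC),
    removes eddy-current baseline offsets with a static background region,
    reconstructs the 32-point volumetric flow curve, and computes stroke
    volumes at the aqueduct of Sylvius and the cervical subarachnoid space
    together with their ratio. Includes a synthetic phantom generator with
    analytically known ground truth, a three-timepoint cohort simulator,
    and paired longitudinal statistics (enumeration-exact Wilcoxon
    signed-rank and paired t tests) for pre/post-shunt comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
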