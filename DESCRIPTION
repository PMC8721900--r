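Package: stridestab
Title: Stride-by-Stride Gait Stability Under Small Treadmill Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates treadmill walking trials with small stride-by-stride
    belt-speed (stick/slip) and medial-lateral platform-shift perturbations,
    and analyses them with a tested pipeline: zero-phase Butterworth
    filtering, kinematic gait-event detection, margin of stability (MOS),
    base of support (BOS) and extrapolated center of mass (XCOM) in the
    anterior-posterior and medial-lateral directions, protocol phase
    labelling with catch strides, and repeated-measures ANOVA with Tukey HSD
    post hocs, paired t tests and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
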