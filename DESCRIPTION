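Package: betadose
Title: Stepwise-Stimulation Beta-Band Suppression Analysis for Chronic STN-LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic subthalamic local field potential
    (LFP) recordings during stepwise deep brain stimulation (monopolar
    review). Quantifies stimulation dose-dependent suppression of beta-band
    (13-35 Hz) power via Morlet wavelet time-frequency decomposition and
    total-sum normalization, relates it to finger-tapping velocity from
    3-axis accelerometry, and provides paired Monte-Carlo permutation tests,
    mixed-effects dose-response and biomarker-velocity models with BIC
    comparison, and post-cessation baseline-recovery profiling. Includes a
    synthetic session generator with known ground truth (1/f background,
    bursting beta oscillator with exponential dose-dependent suppression,
    line noise, ECG and stimulation-aliasing artifacts, beta-coupled tapping
    bursts) standing in for sensing-enabled implantable pulse generator
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
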