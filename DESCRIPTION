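Package: dppghb
Title: Hemoglobin Estimation from Descending-Aortic Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for continuous, noninvasive
    hemoglobin (Hb) monitoring from transesophageal descending-aortic
    photoplethysmography (dPPG). Provides a synthetic-data generator for
    two-wavelength (red/infrared) dPPG waveforms and hemodilution-transfusion
    Hb trajectories with known ground truth; signal processing to extract
    per-beat AC/DC metrics from raw waveforms (FIR bandpass filtering, beat
    detection, stable-run selection); stepwise linear regression of reference
    Hb on the AC/DC ratios together with a fixed published two-wavelength
    model; and a full method-comparison battery: Pearson correlation,
    transfusion-trigger ROC with Youden cut-offs, Bland-Altman limits of
    agreement with a repeated-measures variance-components adjustment,
    percentage error, polar-plot trending concordance, three-zone clinical
    error-grid classification, and limits-of-agreement sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
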