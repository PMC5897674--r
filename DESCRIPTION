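Package: micromov
Title: Micro-Movement Spike Trains and Gamma-Process Signatures for
    Biophysical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts continuous biophysical waveforms (hand kinematics,
    electrocardiogram) into unit-less micro-movement spike trains by
    normalizing local peak amplitudes and inter-peak timings, estimates
    personalized Gamma-process signatures by maximum likelihood with
    confidence intervals and noise-to-signal ratios, and tracks
    distributional shifts across experimental conditions on the Gamma
    shape-scale parameter plane. Includes ECG R-peak detection and
    inter-beat-interval extraction, goal-directed versus spontaneous
    movement segmentation, Freedman-Diaconis histograms,
    Kolmogorov-Smirnov shift testing, log-log power-law scatter fits,
    and a ground-truthed synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    MASS,
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
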