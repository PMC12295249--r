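Package: pulsekit
Title: Pulse-Timing Analysis of Synchronized ECG, Arterial Pressure and
    Bioimpedance Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting pulse-timing features from simultaneously
    recorded electrocardiogram (ECG), central aortic pressure (CAP), radial
    artery pressure (RAP) and radial electrical bioimpedance (EBI) waveforms.
    Implements Savitzky-Golay smoothing and derivative estimation, baseline
    removal by minima interpolation or Hankel (trajectory matrix) low-rank
    decomposition, slope-threshold beat onset detection, synchronized
    beat-ensemble construction with three-step outlier rejection (length
    filter, PCA reconstruction error, empirical-copula tail scores),
    ensemble averaging, fiducial point detection (onset B, maximum upstroke
    slope C, peak or inflection D, systolic maximum F, dicrotic notch G),
    and per-patient timing features: pulse arrival time (PAT), pulse transit
    time (PTT), pulse wave velocity (PWV) and the complementary pulse wave
    velocity (CPWV) surrogate. A synthetic-recording generator with dense-grid
    ground truth supports validation end to end, and cohort-level helpers
    provide Spearman correlations with confidence intervals and exact
    rank-sum group comparisons.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
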