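Package: locomode
Title: Lower-Limb Locomotion-Mode Recognition from Fused sEMG and IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recognition of lower-limb locomotion intent from multichannel surface
    electromyography (sEMG) and inertial measurement unit (IMU) recordings. Provides a
    labelled synthetic gait-signal generator over a 13-mode taxonomy (five steady-state
    modes and eight transitions), zero-phase Butterworth preprocessing, bidomain feature
    extraction (MAV, RMS, VAR, median and mean power frequency), kernel principal
    component analysis with an RBF kernel, a sparrow search metaheuristic with chaotic
    opposition-based initialisation, adaptive follower weighting and hybrid mutation for
    tuning support vector machine hyperparameters, and evaluation protocols: bootstrap
    confidence intervals, confusion matrices, noise-robustness sweeps, modality ablation
    and streaming window-by-window prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
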