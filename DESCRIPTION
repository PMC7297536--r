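Package: pupilddm
Title: Pupil-Linked Arousal and Decision Bias with Drift Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how phasic arousal, read out from the pupil,
    relates to bias in perceptual and memory-based choices. Provides a
    synthetic-data generator with a known arousal-to-drift-bias coupling
    (go/no-go mini-block and yes/no designs, pupil traces built from
    impulse responses, blinks and noise), pupillometry preprocessing
    (interpolation, filtering, deconvolution of blink and saccade responses,
    derivative-based phasic scalars and equal-population binning),
    signal-detection metrics including a composite-distribution overall-bias
    statistic, a drift diffusion model simulator and quantile G-square
    fitter with optional hyperbolically collapsing bounds, simulation
    experiments on the drift-rate-variability confound and on alternative
    bias mechanisms, and group-level mixed-model and permutation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    signal,
    Matrix,
    lme4,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
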