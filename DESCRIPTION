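Package: pcgewt
Title: Diastolic Heart-Sound Analysis via the Empirical Wavelet Transform
Version: 0.1.0
Authors@R: person("PCG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for grading coronary artery stenosis from diastolic heart
    sounds. Provides wavelet-threshold denoising, second-heart-sound (S2)
    detection and fixed-window diastole extraction, a three-band Meyer-type
    empirical wavelet transform (0-150, 150-500, >500 Hz), band spectral-energy
    features e(1)-e(3) with ratios P1 and P2, nonparametric group statistics
    including the DeLong AUC comparison, participant-wise SVM and gradient
    boosting classification, and a synthetic phonocardiogram cohort generator
    with ground-truth event times for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
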