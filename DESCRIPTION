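Package: sleepstager
Title: Multimodal Sleep-Stage Classification from Actigraphy, Heart Rate
    Variability, and Respiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for sleep-stage classification from
    unobtrusive overnight recordings: preprocessing of actigraphy counts,
    RR-interval series and respiration waveforms; ECG-derived respiration
    (EDR) via R-peak/trough amplitudes; windowed actigraphy, heart rate
    variability and respiratory rate variability feature extraction on a
    30-second epoch grid; leakage-safe participant-grouped model training
    for classical and recurrent sequence classifiers at three stage
    granularities and four modality combinations; Matthews-correlation
    centred evaluation with rank-sum comparisons; and a synthetic
    overnight-cohort simulator with stage-conditioned activity, cardiac,
    respiratory and ECG emission models so the whole pipeline is testable
    without access to restricted polysomnography datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    nnet,
    pracma,
    ranger,
    rpart,
    signal,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
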