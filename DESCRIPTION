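Package: pigwatch
Title: Early Warning of Tail-Biting Events in Finisher-Pig Pens from Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for predicting tail-biting events in pens of finisher
    pigs from hourly water-usage and pen-temperature sensor streams. Each
    stream is filtered with a univariate dynamic linear model (linear trend
    plus three harmonic waves, discount-factor evolution, Kalman updates)
    whose standardized one-step forecast errors feed daily summary features.
    Small feed-forward neural classifiers, a fixed-probability logistic model
    of weekly risk from pen treatments, and a Bayesian ensemble of binary
    alarms combine into pen-day alarm probabilities, evaluated both by
    pair-matched pen classification and by a day-level protocol with 3-day
    pre-event alarm clustering (ROC/AUC with Hanley-McNeil confidence
    intervals). A seeded synthetic barn simulator generates pens, treatment
    assignments, diurnal sensor streams, event schedules and pre-event
    deviations so every stage is testable without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
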