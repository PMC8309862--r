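Package: pestcast
Title: Weather-Driven Forecasting of Pest Insect Appearance with
    Time-Tolerant Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the daily appearance of trap-monitored pest insects
    (the cotton bollworm, Helicoverpa armigera, is the motivating species)
    from lagged air-temperature and relative-humidity series, using a bank
    of nine standard classifiers over a 21-variable feature window
    (day-of-year plus ten days of temperature and humidity history).
    Forecasts are scored with confusion-matrix metrics and with
    time-tolerant windowed hit and false-prediction statistics that credit
    a predicted-positive day if a real occurrence falls within a forward
    window of one, three or five days. Includes a seasonal weather and
    occurrence simulator with known logistic hazards for benchmarking and
    parameter-recovery studies, a fixed daily CSV schema, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    MASS,
    nnet,
    randomForest,
    rpart,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
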