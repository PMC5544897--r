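Package: idioplan
Title: Idiographic Treatment Planning and Process Monitoring for Symptom Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns a single patient's intensive repeated-measures symptom
    time series (ecological momentary assessment) into per-symptom
    treatment-priority scores. The pipeline runs exploratory P-technique
    factor analysis with oblimin rotation, confirmatory factor analysis
    gated on Hu-Bentler fit criteria, vector-autoregressive modeling of
    the factor-score series with AIC lag selection, and a scoring algebra
    that combines within-time (loading-based) and between-time
    (lagged-R-squared) explained variance into normalized factor and
    symptom priority scores. Also provides psychotherapy
    process-monitoring statistics (moving-window dynamic complexity,
    recurrence matrices, LOESS trend curves with confidence bands, weekly
    percent-change outcomes) and a synthetic-patient simulator with
    retained ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
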