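Package: mobimood
Title: Digital Phenotyping of Mood from Smartphone and Wearable Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for predicting depression, anxiety and stress
    severity from passively sensed behaviour. Cleans raw GPS streams and
    extracts the classic mobility features (total distance, location
    variance, location entropy, normalized entropy, homestay), converts
    screen events into phone-usage frequency and duration, validates and
    aggregates wearable daily summaries (steps, MET, sleep architecture,
    RMSSD) and momentary mood reports, scores the DASS-21 into its three
    subscales with standard severity cut-offs, pools daily features into
    two-week windows aligned with repeated assessments, and fits
    random-intercept/random-slope linear mixed models under multilevel
    predictive-mean-matching multiple imputation with Rubin pooling and
    pooled likelihood-ratio model comparison. A synthetic cohort generator
    with planted standardized effects and missing-at-random masking makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
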