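Package: addhrvr
Title: Person-Specific Detection of Additional (Non-Metabolic) Heart Rate
    Variability Reductions from Ambulatory Recordings
Version: 0.1.0
Authors@R:
    person("Ambulatory", "Psychophysiology Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects prolonged additional reductions in heart rate variability
    (AddHRVr) -- periods where 30-s RMSSD falls below the level predicted from
    concurrent body movement -- in ambulatory interbeat-interval and
    accelerometry recordings. Provides interbeat-interval artifact cleaning and
    30-s epoching, person-specific inverse calibration of RMSSD on acceleration
    with fit-quality exclusion gates, SE-based thresholding with run-length
    episode detection and hourly coding, within/between-person decomposition of
    hourly codes with person-level association summaries, a seeded
    synthetic-data generator with planted suppression episodes for end-to-end
    validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
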