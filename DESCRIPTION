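Package: toddleracc
Title: Toddler Accelerometry Simulation, Activity Counts, and Behavior
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing hip- and wrist-worn triaxial accelerometer
    data recorded while toddlers perform everyday behaviors such as walking,
    crawling, climbing, riding in a stroller, or being carried by an adult.
    Provides a seeded generator of behavior-specific triaxial signals and
    annotation tracks, an open per-epoch activity-count algorithm with
    cut-point utilities, behavior-label filtering and inter-coder agreement,
    extraction of 78 time- and frequency-domain window features, d-prime
    (sensitivity index) feature ranking, and a random-forest classifier that
    separates the "carried" behavior from ambulation under
    leave-one-subject-out cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
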