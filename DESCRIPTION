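Package: goalfun
Title: Goal Functions for In-Place Virtual-Reality Motor Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design and analysis of unconstrained in-place motor tasks built on
    explicit goal functions that map a trial's execution variables to a scalar
    performance error. Implements three virtual-reality tasks (bow-and-arrow,
    reach-and-strike, punching bag) with ballistic and pendulum physics, the
    tolerance-noise-covariation (TNC) decomposition of mean error into
    centroid-location, trial-to-trial-variability, and covariation components,
    a three-step subject-specific task-adjustment procedure (velocity scaling,
    target resizing, deterministic visual error modification with
    solution-manifold projection), target-frame performance metrics, trial
    filters, a seeded synthetic-data generator, and CSV/YAML/JSON file formats
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
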