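Package: tdrcapture
Title: Capture Behaviour and Physiological Stress from Longline Time-Depth Recorders
Version: 0.1.0
Authors@R:
    person("Packaged", "Analysis", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the capture behaviour of sharks hooked on demersal
    longlines from time-depth-recorder (TDR) depth traces: detects the capture
    point, builds a tide-corrected baseline schedule, identifies movement bouts
    against gangion-extension thresholds and summarises time spent moving.
    Pairs the behavioural pipeline with Bayesian additive linear regression
    (Gibbs sampling) of blood-biochemistry stress markers on capture duration
    and sea-surface temperature, credibility-interval significance, and
    BEST-style two-group difference estimation. Includes seeded synthetic-data
    generators for both depth traces (with known ground truth) and blood
    cohorts, plus a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
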