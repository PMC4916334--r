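Package: walkcounts
Title: Walking Recognition and Physical Activity Level Estimation from
    Triaxial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects walking in raw triaxial accelerometer recordings by
    matching each 5-second epoch against a personalized gait template and
    scoring two features (signal standard deviation and the standard
    deviation of the template cross-correlation) with a naive Bayes
    likelihood model calibrated on a treadmill session.  Converts
    acceleration to activity counts by detrending, rectifying and
    integrating each axis, segments walking into short (<1 min) and long
    bouts, validates wear days, and aggregates daily and subject-level
    summaries of non-walking, short-walk and long-walk activity.  Includes
    linear and stepwise regression models that predict physical activity
    level (PAL, the ratio of total energy expenditure to basal metabolic
    rate) from daily count categories, and a synthetic accelerometry and
    cohort generator with ground-truth labels so the whole pipeline can be
    exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
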