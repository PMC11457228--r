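Package: growthspurt
Title: Pubertal Growth Spurt Analysis with a Shape-Invariant Growth Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Fits the SITAR (SuperImposition by Translation And Rotation)
    shape-invariant growth model to mixed-longitudinal height data using a
    natural cubic spline mean curve with per-subject size, tempo and velocity
    random effects, extracts the five pubertal growth-spurt parameters (age
    and velocity at spurt onset, age and magnitude of peak height velocity,
    and the growth spurt interval) from individual velocity curves, and
    summarises them as centile tables, random-effect correlation matrices and
    top-versus-bottom quintile contrasts. Includes a calibrated synthetic
    cohort generator for sex-specific mixed-longitudinal height data so the
    full pipeline can be exercised and validated without access to the
    original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
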