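Package: fdopt
Title: Two-Level Factorial Optimization of Forced Degradation and
    Chromatographic Method-Validation Statistics
Version: 0.1.0
Authors@R:
    person("Analytical", "Methods Lab", email = "methods@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and analysing 2^k full factorial
    forced-degradation experiments: design construction in standard
    (Yates) order, coded/actual factor-level transformation, saturated
    coefficient estimation by orthogonal contrasts, the Yates tabular
    algorithm, significance screening against a pooled high-order error
    term, model reduction, and closed-form inversion of the fitted model
    to find stress settings that hit a target percent degradation
    (contour data). Also implements the companion method-validation
    statistics: least-squares calibration, percent relative standard
    deviation, and the within-day/between-day one-way ANOVA F-test for
    intermediate precision. Includes seeded synthetic-data generators so
    the whole pipeline is testable without laboratory data, plus CSV/JSON
    readers, writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
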