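Package: breadrisk
Title: Probabilistic Human Health Risk Assessment for Toxic Elements in Bread
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic human health risk assessment for
    dietary exposure to arsenic and other potentially toxic elements in bread,
    following the U.S. EPA chronic-daily-intake framework. Computes hazard
    quotients, hazard indices, carcinogenic risks and their classifications
    from bakery-survey concentration tables; screens mean concentrations
    against regulatory limits; decomposes the bread burden into flour, dough
    and oven-contact contributions; runs the survey's inferential group
    comparisons (Kolmogorov-Smirnov normality gate, then one-way ANOVA or
    Kruskal-Wallis); propagates input uncertainty by seeded Monte Carlo
    simulation; and ranks inputs by contribution to output variance. A seeded
    synthetic-study generator reproduces the statistical structure of a
    multi-region bakery survey (five regions, three production stages, twelve
    elements, left-censored mercury and lead) so the full pipeline is testable
    without access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
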