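Package: crsafety
Title: Simulation of Competing-Risks Safety Analyses in Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the choice between cause-specific (Cox) and
    subdistribution (Fine-Gray) hazard regression changes the conclusions of
    adverse-event analyses when death acts as a competing risk. Provides a
    seeded simulator of two-arm trials with exponential latent event times and
    administrative censoring, native Newton-Raphson fitters for both regression
    settings with a single binary treatment covariate, Kaplan-Meier,
    Nelson-Aalen and Aalen-Johansen non-parametric estimators, Rubin's-rules
    pooling of replicated fits, and a grid experiment driver that classifies
    every simulated condition into superiority, inferiority or equivalence and
    into the nine outcome-switching categories, with tidy table and heat-map
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    ggplot2,
    optparse
Config/testthat/edition: 3
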