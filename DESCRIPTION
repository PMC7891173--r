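Package: beeflow
Title: Gene-Flow Models of Response to Selection in Honeybee Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the response to selection of a honeybee population split into a
    selected breeding population and an unselected passive population that benefits
    from genetic migration. Implements the year-by-year gene-flow recursions for mean
    true breeding values under uncontrolled and controlled (mating-station) mating,
    closed-form asymptotic predictors of annual genetic gain, genetic lag and time lag,
    characteristic-root convergence analysis of the recursions, a stochastic
    individual-based breeding-program simulator (queens, haploid drones, worker groups,
    truncation selection, sister-group mating stations), and a validation pipeline that
    regresses simulated against predicted genetic progress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
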