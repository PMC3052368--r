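Package: dgrecruit
Title: Age-Dependent Recruitment of Adult-Born Dentate Gyrus Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model of when adult-born dentate gyrus granule
    neurons participate in spatial information processing. Fits a linear
    age-dependent responsiveness probability to Arc-expression data,
    a power-law decline of cohort survival anchored to an observed
    BrdU-labelled cohort, and convolves the two over the animal's life
    span to predict the number of adult-born neurons recruited by spatial
    exploration at each age, including the early non-specific Arc
    expression background and the census arithmetic that scales sampled
    cell counts to population-level predictions. Ships a synthetic-data
    generator emulating BrdU/Arc pulse-chase count tables so every stage
    of the pipeline is testable without external data, plus seeded
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
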