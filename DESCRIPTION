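Package: wolbtrace
Title: Tracing Invasion Origins from Spatially Varying Wolbachia Infection Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers candidate geographic origins of invasive insect
    populations from the spatial structure of endosymbiont infection
    frequencies in the native range. Provides infection-frequency
    estimation with Wilson (and Clopper-Pearson) binomial confidence
    intervals, pairwise Fisher exact comparisons, empirical and
    directional semivariograms with weighted least-squares fitting of the
    exponential variogram model, ordinary kriging of infection frequency
    with prediction variance and leave-one-out cross-validation, a
    binomial compatibility score that ranks grid cells as candidate
    origins of an uninfected invasive sample, and a seeded simulator of
    spatially autocorrelated infection-frequency surfaces with binomial
    site sampling for parameter-recovery experiments. All user-facing
    functions take data frames and return tibbles so stages compose with
    the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    geosphere,
    minpack.lm,
    jsonlite,
    withr,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
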