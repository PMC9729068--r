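Package: misflow
Title: Gene Flow Under Misspecified Coalescent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic tools for studying what happens when continuous gene flow
    between two species (isolation-with-migration, isolation-with-initial-migration,
    and secondary-contact models) is analysed under an episodic introgression
    (MSci) model. Provides closed-form coalescent-time densities and pairwise
    sequence likelihoods under the Jukes-Cantor model, Kullback-Leibler
    minimisation to obtain pseudo-true introgression parameters, a structured
    coalescent simulator on species networks with migration bands and
    introgression nodes, and maximum-likelihood fitting of two-species models to
    per-locus pairwise difference counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
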