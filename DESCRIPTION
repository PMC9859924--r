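Package: beansim
Title: Stochastic Simulation of Dry Bean Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of closed-system dry bean (Phaseolus
    vulgaris) breeding programs. Provides a multi-linkage-group genetic map
    emulator with Haldane recombination, additive QTL trait architectures for
    days to flowering, white mold tolerance and seed yield built from published
    effect sizes, drift-based founder populations carrying linkage
    disequilibrium, five classical selection strategies (mass, bulk, single
    seed descent, pedigree, modified pedigree) under three breeding frameworks
    (conventional, speed breeding, genomic selection with ridge-regression
    marker effects), and the standard per-cycle outputs: adjusted genetic gain,
    favorable-allele fixation, Hamming distance to the ideotype, additive
    variance and effective population size, plus a run-level principal
    component report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
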