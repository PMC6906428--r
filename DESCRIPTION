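Package: seedfillr
Title: Logistic Seed-Filling Traits, QTL Mapping and Bulked Segregant
    Analysis for Biparental Maize Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits logistic growth curves to developing-seed dry-weight
    trajectories and derives twelve closed-form seed-filling traits
    (final weight, filling rates, phase durations and phase
    accumulations).  Provides multi-environment trait statistics
    (variance components, broad-sense heritability, BLUP shrinkage,
    correlations), recombinant-inbred-line marker quality control,
    sliding-window bin-map construction, Kosambi genetic distances,
    composite interval mapping with an effective-number-of-tests
    (Li-Ji) genome-wide threshold, and bulked-segregant statistics
    (TMM normalization, negative-binomial exact tests, SNP index,
    G statistic, Fisher tests).  A synthetic-data generator emulates a
    biparental RIL study end to end so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
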