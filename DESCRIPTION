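Package: ldldur
Title: Linear Discriminative Learning Measures for Modeling Acoustic Word
    Durations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the mapping between word form and word
    meaning shapes spoken word durations, using linear discriminative
    learning (LDL). The package builds binary triphone cue matrices and
    real-valued semantic matrices for a lexicon under three network
    architectures (idiosyncratic, morphology, base), solves the
    comprehension and production mappings with the Moore-Penrose
    generalized inverse, derives per-word network measures (path sum, mean
    word support, path entropies, semantic vector length, semantic
    density, target correlation), constructs the duration-difference
    response from baseline durations, and fits, trims, and simplifies
    standard and mixed-effects duration regressions with lmg
    relative-importance decomposition. A synthetic-lexicon module
    generates lexicons, lexome vector stores, segment duration tables,
    and token durations with known ground truth so the whole pipeline is
    verifiable by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
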