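Package: ventviromics
Title: Comparative Biogeography of Hydrothermal Vent Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparative viral biogeography of
    deep-sea hydrothermal vent viromes. Curates viral genome bins (vMAGs) with
    redundancy and lifestyle screening, estimates pairwise genome ANI with
    aligned fractions by fragment mapping, clusters genomes with a from-scratch
    Markov Clustering (MCL) implementation on aligned-fraction-normalized ANI
    scores, classifies clusters geographically (endemic, intra-field,
    inter-field), clusters viral proteins by greedy set cover on an
    identity/coverage graph with cross-site sharing statistics, detects viruses
    across samples by covered fraction with per-sample normalized relative
    abundance, quantifies host-virus abundance congruence with clr-based
    proportionality (rho), and closes the dataset accounting ledger. A
    synthetic multi-site community generator with planted cluster structure,
    protein families, and host-coupled abundances provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
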