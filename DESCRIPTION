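Package: ppirewire
Title: Differential Protein-Protein Interaction Network Rewiring from AP-MS SILAC Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative differential interactome analysis of
    affinity-purification mass-spectrometry (AP-MS) experiments with SILAC
    quantification. Scores bait-prey interactions against empty-vector
    controls (one-sided location test plus the percentile-based
    significance-A outlier statistic), classifies interaction rewiring
    between two cellular conditions (gained, lost, abundance-shifted,
    unchanged), assembles condition and differential spoke-model networks
    with topology metrics, solves an equilibrium model of effectors
    competing for the single effector-binding site of an active GTPase,
    scores damped random-walk information flow from a source node to sink
    transcription factors (channel model), and tests hypergeometric
    enrichment of protein sets in networks together with protein-complex
    coverage. A seeded synthetic-data generator emulates the full study
    design (95 baits, label-swapped replicates, planted rewiring) so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
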