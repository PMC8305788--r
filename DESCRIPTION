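Package: netpharm
Title: Prognosis-Conditioned Gene Dependency Networks and Network-Based
    Precision Drug Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene dependency networks from binarized tumour
    expression profiles and survival-derived prognostic risk labels using
    conditional mutual information with an empirical random-pair null, ranks
    genes per patient with a directed GeneRank propagation seeded by
    fold-changes against healthy controls, scores candidate drugs and drug
    combinations by one-sided Kolmogorov-Smirnov enrichment of their targets
    among top-ranked genes, screens subtype-specific combinations with exact
    binomial tests, evaluates treatment splits by log-rank tests and Cox
    hazard ratios, and quantifies in-vitro drug synergy with the Chou-Talalay
    median-effect model (combination index and dose-reduction index). Includes
    a synthetic cohort generator with planted dependencies, driver genes, and
    drug-target sets so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
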