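Package: genetrace
Title: Gene-Family Reconciliation and Genome Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary views of comparative genome evolution
    in a fixed species phylogeny. The gene-family track screens homologs by
    exact local alignment, builds neighbor-joining gene trees with bootstrap
    supports, and reconciles them with a species tree by duplication-loss
    parsimony, including support-threshold contraction, exhaustive rooting,
    minimum-cost polytomy resolution, likelihood-based candidate filtering
    (Shimodaira-Hasegawa test via RELL), extended majority-rule consensus,
    and per-node event supports. The structural track models genomes as
    signed gene orders and provides double-cut-and-join (DCJ) distances,
    sorting scenarios, median-based ancestor inference, Nei-Gojobori Ks
    estimation, and ortholog/out-paralog classification. Fully seeded
    simulators for birth-death gene families with protein sequence
    evolution and for genome divergence by random DCJ operations provide
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
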