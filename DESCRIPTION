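Package: contactdiff
Title: Ensemble Contact-Map Perturbation Analysis of Missense Mutations
    in Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how a point mutation perturbs a protein complex by
    comparing residue-contact maps across ensembles of structural models.
    Computes binary heavy-atom contact maps under a strict distance cutoff,
    averages them into per-pair contact frequencies over a scored model
    ensemble, differences wild-type against mutant frequencies, annotates
    pairs whose contact status changes in more than a threshold fraction of
    models, and places color-coded pseudo-atom "beads" in inter-residue
    space for structural visualization. Also detects hydrogen bonds and
    salt bridges with explicit geometric criteria, maps residue positions
    between homologs through a sequence alignment, and generates synthetic
    model ensembles with designed contact perturbations so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
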