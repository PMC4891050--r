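Package: phorescreen
Title: Structure-Based Pharmacophore Screening and Hit Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale structure-based virtual screening cascade for
    protein-protein interaction pockets. Generates Ludi-style interaction
    maps (complementary hydrogen-bond donor, acceptor and hydrophobic
    features plus exclusion volumes) from a binding-site sphere on a parsed
    protein structure, clusters features and enumerates 3-7-feature
    pharmacophore hypotheses, matches ligand libraries against them with
    Kabsch superposition and a quadratic-falloff fit score, scores poses
    with a transparent Lennard-Jones/Coulomb energy model including
    per-residue decomposition and hydrogen-bond detection, applies
    property filters and ranked funnel cuts with fingerprint-based
    diversity selection, and triages experimental screen readouts
    (SPR response units, MMP-2 inhibition ratios, densitometry, and
    four-parameter logistic dose-response fits). Deterministic synthetic
    generators provide toy pockets, planted ligand libraries, screen
    tables and dose-response data so the full funnel is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    minpack.lm,
    bio3d,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
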