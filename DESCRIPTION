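Package: rapidmine
Title: Full-Dataset Mining of mRNA-Display Selection Sequencing Data
Version: 0.1.0
Authors@R:
    person("Rik", "Veldhuis", email = "rik.veldhuis@posteo.net",
           role = c("aut", "cre"))
Description: Tools for analysing next-generation sequencing output of mRNA-display
    (RaPID) macrocyclic peptide selections without abundance cut-offs. Decodes
    amplicon reads under a reprogrammed genetic code (NNK random region, thioether
    macrocyclisation onto a downstream cysteine), counts and ranks unique peptides
    per selection round, condenses entire rounds by greedy incremental identity
    clustering with a short-word prefilter, progressively aligns cluster
    representatives, scores per-column conservation, extracts conserved sequence
    families with consensus motifs, names hits by the library/cluster/rank
    convention, and proposes macrocycle-only truncations from conservation
    profiles. Ships a multi-round selection simulator with planted binder
    families, fitness-driven enrichment and sequencing error so that every stage
    is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
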