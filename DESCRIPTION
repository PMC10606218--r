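Package: conformoscope
Title: Conformer-Ensemble Cartography and In Silico Mutagenesis of
    Alternating-Access Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for ensembles of predicted single-chain
    transporter structures built on the LeuT fold. Reads CA-level PDB
    models, computes per-residue RMSD deviation profiles under a single
    global Kabsch superposition, scores all-against-all structural
    similarity with a Dali-style elastic distance-matrix score, embeds
    conformer pools by correspondence analysis and classifies models as
    outwardly open, inwardly open or intermediate against anchor
    structures. Builds residue-interaction networks with per-state
    consensus communities, classifies in silico mutants as
    switched/partial/silent with epistasis scores, detects clade-specific
    alignment columns (type-ii rate shifts, Sequence-Harmony and
    Multi-Relief style group-specific sites), matches PROSITE-style
    sequence patterns, and tests 3D colocalization of site sets by
    permutation. A seeded rocking-bundle generator provides synthetic
    ensembles, mutation-response structures and grouped alignments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
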