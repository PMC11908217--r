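Package: thermocontact
Title: Temperature-Sensitive Contact Analysis of Protein Conformational Ensembles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how residue-residue contacts in proteins respond to
    temperature, from conformational ensembles sampled over an ordered
    temperature ladder. Detects typed noncovalent contacts (salt bridges,
    hydrophobic contacts, hydrogen bonds, cation-pi and pi-stacking) per
    frame, aggregates them into contact-frequency x temperature matrices,
    and extracts temperature-sensitive contact modes by principal component
    analysis, classifying them as melting or forming. Builds
    temperature-averaged hydrophobic interaction networks and scores
    residues by closeness centrality, computes per-residue RMSF and a
    temperature-sensitivity score, per-column Shannon conservation entropy
    from multiple sequence alignments, and integrates entropy, flexibility
    and centrality into per-residue k-means clusters. Includes a synthetic
    ensemble generator with planted ground truth so every stage can be
    validated without molecular dynamics simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
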