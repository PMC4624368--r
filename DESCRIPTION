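Package: ssnrecruit
Title: Sequence Similarity Networks for Recruiting Highly Divergent
    Environmental Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sequence-similarity-network protocol for discovering highly
    divergent environmental homologs of ancient, rarely transferred gene
    families. Builds filtered similarity networks from BLAST-style tabular
    hits or a built-in local aligner, selects "nucleus" gene families by
    per-domain graph conductance, recruits environmental homologs in
    iterative search rounds, assigns topological class labels, scores each
    environmental sequence by identity to its closest published relative,
    extracts maximal cliques of divergent sequences (Bron-Kerbosch with
    pivoting), and characterizes cliques by average residue identity,
    conserved-block content and Nei-Gojobori (NG86) dN/dS. Ships a
    synthetic-data generator with planted truth so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
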