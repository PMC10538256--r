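Package: mitoforms
Title: Multipartite Mitochondrial Genome Architecture and Isoform Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing multipartite plant mitochondrial
    genomes in which repeat-mediated homologous recombination maintains a
    pool of alternative circular DNA molecules (isoforms). The package
    models the genome as a multigraph of unbreakable segments joined at
    junctions, enumerates all junction-simple circular isoforms together
    with their recombination reaction network, detects direct and inverted
    repeat pairs, estimates per-repeat recombination activity from long
    reads via flank-composition references, counts long-read junction
    support and isoform-unique subpath confirmations, infers per-segment
    copy number from masked short-read depth normalized on single-copy
    nuclear genes, and converts segment copy numbers into subgenome
    stoichiometry with redundant-formulation diagnostics. Seeded synthetic
    data generators emulate a nine-segment eelgrass-like architecture with
    known truth so that every stage can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
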