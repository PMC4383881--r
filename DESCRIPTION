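Package: termikit
Title: Protein Terminus Annotation, Protease Enrichment and Protease-Web Path Finding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for degradomics and N-/C-terminomics (e.g. TAILS) data: a
    flat-file knowledgebase of proteins, terminus evidences, protease cleavage
    and inhibition events; exact 20-residue sequence-context mapping of termini
    and cleavages across protein isoforms and from alternative transcripts and
    translation-initiation sites; an annotation engine that locates submitted
    terminal peptides, classifies their origin (canonical, alternative splicing,
    alternative translation, cleavage, experimental), and computes per-protease
    enrichment statistics (one-sided Fisher exact test with Benjamini-Hochberg
    correction), Venn overlap counts, substrate-protease matrices and
    frequency-based sequence logos; and a protease-web path finder that
    enumerates grammar-valid direct and indirect cleavage/inhibition paths from
    a candidate protease to observed substrates, with ortholog cross-species
    mapping and Graphviz DOT export. Includes a seeded synthetic-knowledgebase
    generator for end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
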