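Package: peptax
Title: Protein-Space Taxonomic Profiling of Shotgun Metagenomics Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Taxonomic profiling of shotgun metagenomics reads through a
    protein-space detour. Reads are translated (six-frame translation or
    externally predicted protein fragments), translations are broken into
    short peptides (overlapping k-mers or non-overlapping tryptic
    peptides), each peptide is looked up in an exact-match index mapping
    peptides from an annotated reference proteome to a modified lowest
    common ancestor (LCA*) consensus taxon, spurious identifications are
    removed with short-peptide, low-frequency and seed-and-extend filters,
    and the surviving identifications are aggregated into one consensus
    taxon per read (pair) with the LCA, LCA*, maximum root-to-leaf (MRTL)
    or hybrid heuristic on an NCBI-style taxonomy. Includes index
    construction from any annotated reference proteome, rank-snapped
    frequency tables, precision and sensitivity evaluation against a truth
    table, and a seeded synthetic-community generator (taxonomy, proteomes,
    reads with substitution errors and shuffled negative controls) for
    self-contained benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
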