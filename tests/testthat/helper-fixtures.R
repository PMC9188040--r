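# Hand-built seven-species-free taxonomy used across the unit tests:
#
#   1 root
#   └─ 2 Bacteria (superkingdom)
#      ├─ 10 GenusA ── 101 speciesA1 ── 1011 strainA1 (no rank)
#      │            ├─ 102 speciesA2
#      │            └─ 103 speciesA3 (valid = FALSE)
#      └─ 11 GenusB ── 111 speciesB1
fixtureTree <- function() {
  taxonomy(
    ids     = c(1L, 2L, 10L, 11L, 101L, 102L, 103L, 111L, 1011L),
    names   = c("root", "Bacteria", "GenusA", "GenusB",
                "speciesA1", "speciesA2", "speciesA3", "speciesB1",
                "strainA1"),
    ranks   = c("no rank", "superkingdom", "genus", "genus",
                "species", "species", "species", "species", "no rank"),
    parents = c(1L, 1L, 2L, 2L, 10L, 10L, 10L, 11L, 101L),
    valid   = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
}

# tiny reference proteome on the fixture tree:
#   SHAREDPEPTIDEK is shared across the two genera (resolves to Bacteria),
#   GENVSPEPT is shared by the two GenusA species (resolves to the genus),
#   the homopolymer tails are species-unique (resolve to the species)
fixtureProteins <- function() {
  data.frame(
    id = c("pA1", "pA2", "pB1"),
    taxon_id = c(101L, 102L, 111L),
    sequence = c("SHAREDPEPTIDEKGENVSPEPTKAAAAAAAAA",
                 "GENVSPEPTCCCCCCCCC",
                 "SHAREDPEPTIDEKGGGGGGGGG"),
    stringsAsFactors = FALSE)
}

writeTempTaxonomy <- function(tax) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeTaxonomy(tax, path)
  path
}
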