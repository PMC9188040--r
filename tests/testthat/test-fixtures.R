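test_that("synthetic taxonomy has the promised shape and is deterministic", {
  spec <- simulationSpec(nGenera = 2L, speciesPerGenus = 2L)
  tx <- makeTaxonomy(spec)
  expect_identical(length(tx), 8L)  # root + domain + 2 genera + 4 species
  expect_identical(sum(tx@ranks == "species"), 4L)
  expect_identical(makeTaxonomy(spec)@ids, tx@ids)
  one <- makeTaxonomy(simulationSpec(nGenera = 1L, speciesPerGenus = 1L))
  expect_identical(length(one), 4L)
  expect_length(lineage(one, one@ids[one@ranks == "species"]), 4L)
})

test_that("proteomes carry genus-conserved domains and round-trip the CDS", {
  spec <- simulationSpec(proteinsPerSpecies = 10L, proteinLen = 60L,
                         seed = 23L)
  tx <- makeTaxonomy(spec)
  pr <- makeProteomes(tx, spec)
  expect_identical(nrow(pr$proteins), 4L * 10L)
  expect_true(all(nchar(pr$proteins$sequence) == 60L))

  # the shared N-terminal half is identical within a genus
  sp <- split(pr$proteins, pr$proteins$taxon_id)
  genusOf <- function(t) tx@parents[match(t, tx@ids)]
  core <- function(df) substr(df$sequence[1], 1, 30)
  byGenus <- split(vapply(sp, core, character(1)),
                   genusOf(as.integer(names(sp))))
  for (g in byGenus) expect_identical(g[[1]], g[[2]])

  # translating the back-translated CDS recovers every protein
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(pr$cds), genetic.code =
      Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
  expect_identical(unname(aa), pr$proteins$sequence)

  # same seed, same proteome; the caller's RNG state is untouched
  set.seed(77); before <- .Random.seed
  pr2 <- makeProteomes(tx, spec)
  expect_identical(.Random.seed, before)
  expect_identical(pr2$proteins$sequence, pr$proteins$sequence)
})

test_that("simulated reads honor rate 0, the shuffle contract, and the seed", {
  spec <- simulationSpec(nReads = 100L, substitutionRate = 0,
                         shuffledFraction = 0.2, proteinsPerSpecies = 5L,
                         proteinLen = 60L, seed = 31L)
  tx <- makeTaxonomy(spec)
  pr <- makeProteomes(tx, spec)
  sim <- simulateReads(pr, spec)
  expect_length(sim$reads, 100L)
  expect_length(sim$shuffled, 20L)
  expect_length(sim$truth, 80L)

  # rate 0: every non-shuffled read is an exact substring of a template
  templates <- c(pr$cds, vapply(pr$cds, function(t)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(t))), character(1)))
  for (id in names(sim$truth)[1:25]) {
    hit <- any(vapply(templates, function(t)
      grepl(sim$reads[[id]], t, fixed = TRUE), logical(1)))
    expect_true(hit)
  }

  # a shuffled read keeps its base multiset
  sim2 <- simulateReads(pr, spec)
  expect_identical(sim2$reads, sim$reads)
  for (id in sim$shuffled[1:5]) {
    bases <- sort(strsplit(sim$reads[[id]], "")[[1]])
    expect_identical(length(bases), nchar(sim$reads[[id]]))
    expect_true(all(bases %in% c("A", "C", "G", "T")))
  }

  # overlong reads are rejected
  tooLong <- simulationSpec(readLen = 1000L, proteinLen = 60L)
  expect_error(simulateReads(pr, tooLong), "read length exceeds")
})

test_that("paired simulation yields mates from the same fragment", {
  spec <- simulationSpec(nReads = 30L, substitutionRate = 0, paired = TRUE,
                         insertMean = 200, insertSd = 10,
                         shuffledFraction = 0, seed = 41L)
  tx <- makeTaxonomy(spec)
  pr <- makeProteomes(tx, spec)
  sim <- simulateReads(pr, spec)
  expect_identical(names(sim$mates), names(sim$reads))
  expect_true(all(nchar(sim$mates) == spec$readLen))
  # the mate pair profiles consistently with its source species
  idx <- buildIndex(pr$proteins, fragmentationParams("kmer", k = 9L), tx)
  prof <- profileReads(sim$reads, idx, tx, preset("max-sensitivity"),
                       mates = sim$mates)
  for (i in seq_len(nrow(prof)))
    expect_true(prof$taxon_id[i] %in%
                  lineage(tx, sim$truth[prof$read_id[i]]))
})

test_that("sensitivity does not increase with the substitution rate", {
  sens <- vapply(c(0, 0.01, 0.05), function(rate) {
    spec <- simulationSpec(nReads = 120L, substitutionRate = rate,
                           shuffledFraction = 0, seed = 59L)
    tx <- makeTaxonomy(spec)
    pr <- makeProteomes(tx, spec)
    sim <- simulateReads(pr, spec)
    idx <- buildIndex(pr$proteins, fragmentationParams("kmer", k = 9L), tx)
    prof <- profileReads(sim$reads, idx, tx, preset("high-precision"))
    evaluateProfiles(prof, sim$truth, tx, "species")$sensitivity
  }, numeric(1))
  # tolerate sampling noise of a few reads
  expect_true(all(diff(sens) <= 0.05))
  expect_gt(sens[1], sens[3])
})
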