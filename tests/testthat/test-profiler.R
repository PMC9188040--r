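tx <- fixtureTree()
kparams <- fragmentationParams("kmer", k = 9L)

test_that("peptide profiling yields one track item per peptide", {
  idx <- buildIndex(fixtureProteins(), kparams, tx)
  tr <- profilePeptides(idx, c("KAAAAAAAA", "QQQQQQQQQ", "GENVSPEPT"),
                        segments = c(1L, 1L, 2L))
  expect_identical(tr$taxon, c(101L, NA, 10L))
  expect_identical(nrow(profilePeptides(idx, character(0))), 0L)
  # all-absent peptides: an all-unidentified track
  tr2 <- profilePeptides(idx, c("QQQQQQQQQ", "YYYYYYYYY"))
  expect_true(all(is.na(tr2$taxon)))
  # fragmentation mismatch with the index metadata is a config error
  expect_error(profilePeptides(idx, "KAAAAAAAA",
                               params = fragmentationParams("kmer", k = 8L)),
               "does not match index")
  expect_error(profilePeptides(idx, "KAAAAAAAA",
                               params = fragmentationParams("tryptic")),
               "mode")
})

test_that("seed-and-extend keeps exact seeds and bridges small gaps", {
  mk <- function(t, seg = 1L)
    data.frame(peptide = paste0("p", seq_along(t)), taxon = t,
               segment = seg, stringsAsFactors = FALSE)
  # exact seed is kept whole
  tr <- mk(c(10L, 10L, 10L))
  expect_identical(seedExtendFilter(tr, 3, 0), tr)
  # no run of s equal taxa: everything dropped
  expect_identical(nrow(seedExtendFilter(mk(c(10L, 10L, NA, NA, 10L)),
                                         3, 1)), 0L)
  # seed extends across a 1-gap onto a differently-identified item
  tr <- mk(c(10L, 10L, 10L, NA, 11L, 10L, 10L))
  expect_identical(seedExtendFilter(tr, 3, 1), tr)
  # but not across a gap wider than g
  tr <- mk(c(10L, 10L, 10L, NA, NA, 11L))
  kept <- seedExtendFilter(tr, 3, 1)
  expect_identical(kept$peptide, c("p1", "p2", "p3"))
  # seeds never span a segment break
  tr <- mk(c(10L, 10L, 10L, 10L), seg = c(1L, 1L, 2L, 2L))
  expect_identical(nrow(seedExtendFilter(tr, 3, 0)), 0L)
  expect_error(seedExtendFilter(tr, 1, 0), "s >= 2")
})

test_that("seed-and-extend matches the exhaustive interval oracle", {
  set.seed(31)
  for (rep in 1:300) {
    len <- sample(2:8, 1)
    t <- sample(c(10L, 11L, NA), len, replace = TRUE)
    seg <- sort(sample(1:2, len, replace = TRUE))
    tr <- data.frame(peptide = paste0("p", seq_len(len)), taxon = t,
                     segment = seg, stringsAsFactors = FALSE)
    s <- sample(2:3, 1); g <- sample(0:2, 1)
    expect_identical(seedExtendFilter(tr, s, g)$peptide,
                     tr$peptide[oracleSeedExtend(tr, s, g)])
  }
})

test_that("seed-and-extend retention is monotone in s and g", {
  set.seed(32)
  for (rep in 1:100) {
    t <- sample(c(10L, 11L, NA), 8, replace = TRUE)
    tr <- data.frame(peptide = paste0("p", 1:8), taxon = t, segment = 1L,
                     stringsAsFactors = FALSE)
    k22 <- seedExtendFilter(tr, 2, 2)$peptide
    expect_true(all(seedExtendFilter(tr, 3, 2)$peptide %in% k22))
    expect_true(all(seedExtendFilter(tr, 2, 0)$peptide %in% k22))
    expect_true(all(k22 %in% tr$peptide))
  }
})

test_that("low-frequency filtering drops rare taxa; minHits 1 is identity", {
  counts <- c(`10` = 3L, `11` = 1L)
  expect_identical(lowFrequencyFilter(counts, 2), c(`10` = 3L))
  expect_identical(lowFrequencyFilter(counts, 1), counts)
  expect_length(lowFrequencyFilter(counts, 5), 0L)
})

test_that("presets encode the six published configurations", {
  p <- preset("tryptic-precision")
  expect_identical(p@translation, "predicted")
  expect_identical(p@fragmentation[c("mode", "minLen", "maxLen")],
                   list(mode = "tryptic", minLen = 5L, maxLen = 45L))
  expect_identical(p@filters$minHits, 2L)
  expect_identical(p@aggregation$method, "mrtl")

  p <- preset("tryptic-sensitivity")
  expect_identical(p@fragmentation$minLen, 9L)
  expect_identical(p@filters$minHits, 1L)

  p <- preset("max-precision")
  expect_identical(p@translation, "predicted")
  expect_identical(p@filters[c("minHits", "seedMin", "gapMax")],
                   list(minHits = 5L, seedMin = 2L, gapMax = 2L))
  expect_identical(p@aggregation, list(method = "hybrid", f = 0.75))

  p <- preset("high-precision")
  expect_identical(p@translation, "sixframe")
  expect_identical(p@filters[c("minHits", "seedMin", "gapMax")],
                   list(minHits = 4L, seedMin = 3L, gapMax = 4L))
  expect_identical(p@aggregation, list(method = "hybrid", f = 0.5))

  p <- preset("high-sensitivity")
  expect_identical(p@filters[c("minHits", "seedMin", "gapMax")],
                   list(minHits = 1L, seedMin = 3L, gapMax = 0L))
  expect_identical(p@aggregation$method, "mrtl")

  p <- preset("max-sensitivity")
  expect_identical(p@filters[c("minHits", "seedMin", "gapMax")],
                   list(minHits = 1L, seedMin = 2L, gapMax = 0L))
  expect_error(preset("ultra-precision"), "unknown preset")
})

test_that("reads profile to their species or an ancestor; misses go to root", {
  spec <- simulationSpec(nReads = 80L, substitutionRate = 0,
                         shuffledFraction = 0, seed = 13L)
  stx <- makeTaxonomy(spec)
  pr <- makeProteomes(stx, spec)
  idx <- buildIndex(pr$proteins, kparams, stx)
  sim <- simulateReads(pr, spec)
  prof <- profileReads(sim$reads, idx, stx, preset("high-precision"))
  expect_identical(prof$read_id, names(sim$reads))
  for (i in seq_len(nrow(prof)))
    expect_true(prof$taxon_id[i] %in%
                  lineage(stx, sim$truth[prof$read_id[i]]))
  # a read with zero index hits maps to the root
  none <- profileReads(c(r = strrep("ACGT", 25)), idx, stx,
                       preset("high-precision"))
  expect_identical(none$taxon_id, 1L)
})

test_that("pair merging pools both mates' identifications across a break", {
  idx <- buildIndex(fixtureProteins(), kparams, tx)
  # mate 1 carries speciesA1 evidence, mate 2 speciesA2 evidence;
  # merged, the pair must aggregate to their genus or deeper
  gc <- Biostrings::getGeneticCode("11")
  revCode <- split(names(gc), gc)
  bt <- function(p) paste(vapply(strsplit(p, "")[[1]],
                                 function(a) revCode[[a]][1], ""),
                          collapse = "")
  m1 <- bt("SHAREDPEPTIDEKGENVSPEPTKAAAAAAAAA")           # speciesA1 evidence
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bt("GENVSPEPTCCCCCCCCC"))))  # speciesA2 evidence
  cfg <- pipelineConfig("sixframe", method = "lca_star")
  single1 <- profileReads(c(r = m1), idx, tx, cfg)
  single2 <- profileReads(c(r = m2), idx, tx, cfg)
  expect_identical(single1$taxon_id, 101L)
  expect_identical(single2$taxon_id, 102L)
  paired <- profileReads(c(r = m1), idx, tx, cfg, mates = c(r = m2))
  expect_identical(paired$taxon_id, 10L)
})

test_that("profiles round-trip through the FASTA-like output format", {
  prof <- data.frame(read_id = c("r1", "r2"), taxon_id = c(101L, 1L),
                     stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".fa")
  writeProfiles(prof, p)
  expect_identical(readProfiles(p), prof)
  pz <- withr::local_tempfile(fileext = ".fa.gz")
  writeProfiles(prof, pz)
  expect_identical(readProfiles(pz), prof)
})
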