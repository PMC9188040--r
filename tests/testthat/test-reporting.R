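tx <- fixtureTree()

prof <- function(ids, taxa)
  data.frame(read_id = ids, taxon_id = taxa, stringsAsFactors = FALSE)

test_that("frequency tables count, snap, and filter", {
  p <- prof(paste0("r", 1:3), rep(101L, 3))
  ft <- frequencyTable(p, tx)
  expect_identical(ft$taxon_id, 101L)
  expect_identical(ft$count, 3L)

  # species-level profiles merge under their genus when snapped
  p <- prof(paste0("r", 1:4), c(101L, 102L, 101L, 111L))
  ft <- frequencyTable(p, tx, rank = "genus")
  expect_identical(ft$taxon_id, c(10L, 11L))
  expect_identical(ft$count, c(3L, 1L))
  expect_true(all(ft$taxon_rank == "genus"))

  # profiles less specific than the rank surface as unassigned (root)
  p <- prof(paste0("r", 1:2), c(2L, 101L))
  ft <- frequencyTable(p, tx, rank = "species")
  expect_identical(ft$taxon_name[ft$taxon_id == 1L], "unassigned")

  # minCount drops singleton rows but counts are conserved beforehand
  p <- prof(paste0("r", 1:5), c(101L, 101L, 102L, 111L, 111L))
  full <- frequencyTable(p, tx)
  expect_identical(sum(full$count), 5L)
  ft <- frequencyTable(p, tx, minCount = 2)
  expect_identical(ft$taxon_id, c(101L, 111L))
  expect_error(frequencyTable(p, tx, rank = "flavour"), "unknown rank")
})

test_that("frequency CSV uses the fixed dialect and quotes commas", {
  tq <- taxonomy(c(1L, 2L), c("root", "Genus, odd name"),
                 c("no rank", "genus"), c(1L, 1L))
  ft <- frequencyTable(prof("r1", 2L), tq)
  p <- withr::local_tempfile(fileext = ".csv")
  writeFrequencyCSV(ft, p)
  lines <- readLines(p)
  expect_identical(lines[1], "taxon_id,taxon_name,taxon_rank,count")
  expect_identical(lines[2], "2,\"Genus, odd name\",genus,1")
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_identical(back$taxon_name, "Genus, odd name")
})

test_that("evaluation implements the confusion-matrix definitions", {
  # 10 reads: 6 correct species, 2 wrong, 2 unassigned, no shuffled
  truth <- setNames(rep(101L, 10), paste0("r", 1:10))
  p <- prof(paste0("r", 1:10),
            c(rep(101L, 6), 102L, 111L, 1L, 1L))
  ev <- evaluateProfiles(p, truth, tx, "species")
  expect_identical(c(ev$tp, ev$fp, ev$fn, ev$tn), c(6L, 2L, 2L, 0L))
  expect_equal(ev$precision, 0.75)
  # false negatives are only the unassigned reads, not the wrong ones
  expect_equal(ev$sensitivity, 6 / 8)
  expect_equal(ev$specificity, 0)  # no shuffled reads: tn = 0, fp > 0

  # all correct, no shuffled
  ev <- evaluateProfiles(prof(paste0("r", 1:4), rep(101L, 4)),
                         setNames(rep(101L, 4), paste0("r", 1:4)),
                         tx, "species")
  expect_equal(ev$precision, 1)
  expect_equal(ev$sensitivity, 1)
  # with no negatives at all, specificity/npv/mcc are undefined -> 0
  expect_setequal(ev$undefined, c("specificity", "npv", "mcc"))
  expect_equal(ev$specificity, 0)

  # all shuffled, none assigned
  ev <- evaluateProfiles(prof(paste0("s", 1:5), rep(1L, 5)),
                         integer(0), tx, "species",
                         shuffled = paste0("s", 1:5))
  expect_identical(ev$tn, 5L)
  expect_equal(ev$specificity, 1)

  # a prediction more specific than the rank is snapped before comparison
  ev <- evaluateProfiles(prof("r1", 1011L), c(r1 = 101L), tx, "species")
  expect_identical(ev$tp, 1L)
  # predictions less specific than the rank count as no assignment
  ev <- evaluateProfiles(prof("r1", 10L), c(r1 = 101L), tx, "species")
  expect_identical(ev$fn, 1L)
  # reads whose truth is less specific than the rank are ignored
  ev <- evaluateProfiles(prof(c("r1", "r2"), c(101L, 101L)),
                         c(r1 = 101L, r2 = 10L), tx, "species")
  expect_identical(ev$n, 1L)
  # orphan reads are an input error
  expect_error(evaluateProfiles(prof("zz", 101L), c(r1 = 101L), tx,
                                "species"), "zz")
})

test_that("evaluation is invariant to read order and mcc stays in [-1, 1]", {
  set.seed(12)
  ids <- paste0("r", 1:30)
  truth <- setNames(sample(c(101L, 102L, 111L), 30, replace = TRUE), ids)
  pred <- sample(c(101L, 102L, 111L, 1L), 30, replace = TRUE)
  p1 <- prof(ids, pred)
  perm <- sample(30)
  ev1 <- evaluateProfiles(p1, truth, tx, "species")
  ev2 <- evaluateProfiles(p1[perm, ], truth, tx, "species")
  expect_identical(ev1[c("tp", "fp", "fn", "tn")],
                   ev2[c("tp", "fp", "fn", "tn")])
  expect_gte(ev1$mcc, -1)
  expect_lte(ev1$mcc, 1)
})

test_that("tree export conserves counts up to the root", {
  p <- prof(paste0("r", 1:5), c(101L, 101L, 102L, 111L, 2L))
  ft <- frequencyTable(p, tx)
  doc <- exportTaxonTree(ft, tx)
  expect_identical(doc$id, 1L)
  expect_identical(doc$subtree_count, 5L)
  sumOk <- function(node) {
    kidSum <- sum(vapply(node$children, `[[`, integer(1), "subtree_count"))
    ok <- node$subtree_count == node$self_count + kidSum
    all(c(ok, vapply(node$children, sumOk, logical(1))))
  }
  expect_true(sumOk(doc))

  # single-species table: a root chain down to that species
  doc1 <- exportTaxonTree(frequencyTable(prof("r1", 101L), tx), tx)
  expect_identical(doc1$subtree_count, 1L)
  node <- doc1
  while (length(node$children)) {
    expect_length(node$children, 1L)
    node <- node$children[[1]]
  }
  expect_identical(node$id, 101L)

  # JSON serialization round-trips the counts
  j <- withr::local_tempfile(fileext = ".json")
  writeTaxonTreeJSON(doc, j)
  back <- jsonlite::read_json(j)
  expect_identical(back$subtree_count, 5L)
})
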