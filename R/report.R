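#' Taxon frequency table of a set of read profiles
#'
#' Counts reads per consensus taxon, optionally snapping every profile to
#' a canonical rank first (counts then merge under the rank-level
#' ancestor; profiles less specific than the rank merge under the root,
#' reported as "unassigned") and dropping taxa observed fewer than
#' `minCount` times.
#'
#' @param profiles data.frame with `read_id`, `taxon_id` (from
#'   [profileReads()]).
#' @param tax a [Taxonomy-class].
#' @param rank optional canonical rank to report at.
#' @param minCount minimum count for a row to be kept (>= 1).
#' @return data.frame with columns `taxon_id`, `taxon_name`,
#'   `taxon_rank`, `count`, sorted by descending count then id.
#' @export
frequencyTable <- function(profiles, tax, rank = NULL, minCount = 1L) {
  stopifnot(nrow(profiles) > 0L, minCount >= 1L)
  ids <- profiles$taxon_id
  if (!is.null(rank))
    ids <- vapply(ids, snapToRank, integer(1), tax = tax, rank = rank)
  counts <- table(ids)
  tid <- as.integer(names(counts))
  pos <- .taxPos(tax, tid)
  out <- data.frame(taxon_id = tid,
                    taxon_name = ifelse(tid == 1L, "unassigned",
                                        tax@names[pos]),
                    taxon_rank = tax@ranks[pos],
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= minCount, , drop = FALSE]
  out <- out[order(-out$count, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a frequency table as CSV
#'
#' Fixed dialect for downstream processing: header
#' `taxon_id,taxon_name,taxon_rank,count`, UTF-8, LF; names containing
#' commas are quoted.
#'
#' @param table data.frame from [frequencyTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyCSV <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  quoteIf <- function(x) ifelse(grepl("[,\"]", x),
                                paste0('"', gsub('"', '""', x), '"'), x)
  writeLines(c("taxon_id,taxon_name,taxon_rank,count",
               paste(table$taxon_id, quoteIf(table$taxon_name),
                     quoteIf(table$taxon_rank), table$count, sep = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Evaluate read profiles against a truth table
#'
#' Confusion-matrix evaluation at a canonical rank. Both prediction and
#' expected taxon are snapped to `rank`; a prediction snapping to the
#' root counts as no assignment. Non-shuffled reads whose expected
#' identification is less specific than `rank` are ignored. Then:
#' true positives are non-shuffled reads assigned to the expected taxon;
#' false positives are non-shuffled reads assigned to a different taxon,
#' or shuffled reads assigned to any taxon; true negatives are shuffled
#' reads left unassigned; false negatives are non-shuffled reads left
#' unassigned.
#'
#' @param profiles data.frame with `read_id`, `taxon_id`.
#' @param truth named integer vector: read id -> expected taxon id
#'   (shuffled reads need no entry).
#' @param tax a [Taxonomy-class].
#' @param rank canonical rank under evaluation.
#' @param shuffled character vector of negative-control read ids.
#' @return A list with counts `tp`, `fp`, `fn`, `tn`, `n` (evaluated
#'   reads), the metrics `precision`, `sensitivity`, `specificity`,
#'   `npv`, `mcc`, and `undefined` naming metrics whose denominator was
#'   zero (reported as 0).
#' @export
evaluateProfiles <- function(profiles, truth, tax, rank,
                             shuffled = character(0)) {
  isShuf <- profiles$read_id %in% shuffled
  known <- isShuf | profiles$read_id %in% names(truth)
  if (!all(known))
    stop(sprintf("read '%s' is neither in the truth table nor shuffled",
                 profiles$read_id[!known][1L]))
  pred <- vapply(profiles$taxon_id, snapToRank, integer(1),
                 tax = tax, rank = rank)
  expSnap <- rep(NA_integer_, nrow(profiles))
  expSnap[!isShuf] <- vapply(truth[profiles$read_id[!isShuf]], snapToRank,
                             integer(1), tax = tax, rank = rank)
  ignore <- !isShuf & expSnap == 1L  # truth less specific than rank
  pred <- pred[!ignore]; expSnap <- expSnap[!ignore]; isShuf <- isShuf[!ignore]
  assigned <- pred != 1L
  tp <- sum(!isShuf & assigned & pred == expSnap)
  fp <- sum((!isShuf & assigned & pred != expSnap) | (isShuf & assigned))
  tn <- sum(isShuf & !assigned)
  fn <- sum(!isShuf & !assigned)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  res <- list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
              precision = rate(tp, tp + fp),
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              npv = rate(tn, tn + fn))
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  res$mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  res$undefined <- names(which(vapply(res, function(x)
    length(x) == 1L && is.na(x), logical(1))))
  for (m in res$undefined) res[[m]] <- 0
  res
}

#' Export a frequency table as a hierarchical tree document
#'
#' Builds a rooted tree suitable for JSON export and interactive
#' visualization: every node carries `id`, `name`, `rank`, `self_count`
#' (reads whose consensus is exactly that taxon), `subtree_count`
#' (self plus all descendants) and `children`. Ancestors of counted taxa
#' appear with `self_count` 0; counts are conserved, so the root's
#' `subtree_count` equals the table's total.
#'
#' @param table data.frame from [frequencyTable()].
#' @param tax a [Taxonomy-class].
#' @return A nested list (the root node).
#' @export
exportTaxonTree <- function(table, tax) {
  stopifnot(nrow(table) >= 0L)
  self <- stats::setNames(table$count, table$taxon_id)
  # all nodes needed: counted taxa plus their ancestors
  need <- unique(unlist(lapply(table$taxon_id, lineage, tax = tax)))
  if (!length(need)) need <- 1L
  build <- function(id) {
    pos <- match(id, tax@ids)
    kids <- tax@ids[tax@parents == id & tax@ids != 1L]
    kids <- sort(intersect(kids, need))
    children <- lapply(kids, build)
    sc <- if (as.character(id) %in% names(self))
            as.integer(self[as.character(id)]) else 0L
    list(id = id,
         name = if (id == 1L) "root" else tax@names[pos],
         rank = tax@ranks[pos],
         self_count = sc,
         subtree_count = sc + sum(vapply(children, `[[`, integer(1),
                                         "subtree_count")),
         children = children)
  }
  build(1L)
}

#' Write the hierarchical tree document as JSON
#'
#' @param tree nested list from [exportTaxonTree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonTreeJSON <- function(tree, path) {
  jsonlite::write_json(tree, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
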