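#' Construct a Taxonomy from per-node vectors
#'
#' Low-level constructor; most users will call [readTaxonomy()] on a
#' five-column taxon table instead.
#'
#' @param ids integer taxon identifiers (must include the root, id 1).
#' @param names character scientific names.
#' @param ranks character ranks ("no rank" allowed).
#' @param parents integer parent identifiers (root is its own parent).
#' @param valid logical validity flags (default all `TRUE`).
#' @param rankOrder canonical rank order, root-most first.
#' @return A validated [Taxonomy-class] object.
#' @export
#' @examples
#' taxonomy(c(1L, 2L), c("root", "Bacteria"), c("no rank", "superkingdom"),
#'          c(1L, 1L))
taxonomy <- function(ids, names, ranks, parents,
                     valid = rep(TRUE, length(ids)),
                     rankOrder = canonicalRanks()) {
  new("Taxonomy",
      ids = as.integer(ids), names = as.character(names),
      ranks = as.character(ranks), parents = as.integer(parents),
      valid = as.logical(valid), rankOrder = as.character(rankOrder))
}

#' Read a taxonomy from a five-column taxon table
#'
#' Parses the tab-separated taxon-table dialect: one node per line with
#' columns `taxon_id`, `name`, `rank`, `parent_id`, `valid`
#' ("true"/"false"), no header. Structural problems (orphan parents,
#' missing root, cycles) are rejected.
#'
#' @param path path to the taxon table (TSV, UTF-8, no header).
#' @param rankOrder canonical rank order, root-most first.
#' @return A validated [Taxonomy-class].
#' @export
readTaxonomy <- function(path, rankOrder = canonicalRanks()) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop(sprintf("malformed taxon table row at line %d: expected 5 fields, got %d",
                 bad[1L], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  ids <- suppressWarnings(as.integer(m[, 1L]))
  parents <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(ids) || anyNA(parents))
    stop(sprintf("malformed taxon table row at line %d: non-integer id",
                 which(is.na(ids) | is.na(parents))[1L]))
  taxonomy(ids, m[, 2L], m[, 3L], parents,
           valid = m[, 5L] %in% c("true", "TRUE", "1"),
           rankOrder = rankOrder)
}

#' Write a taxonomy as a five-column taxon table
#'
#' @param tax a [Taxonomy-class].
#' @param path output path (TSV, no header, LF line endings).
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(tax, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(tax@ids, tax@names, tax@ranks, tax@parents,
                   ifelse(tax@valid, "true", "false"), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

.taxPos <- function(tax, id, what = "taxon") {
  pos <- match(as.integer(id), tax@ids)
  if (anyNA(pos))
    stop(sprintf("unknown %s id: %s", what,
                 paste(id[is.na(pos)], collapse = ", ")))
  pos
}

#' Lineage of a taxon
#'
#' Returns the path of taxon ids from the root (id 1) down to `id`,
#' root first.
#'
#' @param tax a [Taxonomy-class].
#' @param id a single taxon id present in the tree.
#' @return Integer vector of taxon ids; first element is 1, last is `id`.
#' @export
#' @examples
#' tx <- taxonomy(c(1L, 2L, 7L), c("root", "Bacteria", "Escherichia"),
#'                c("no rank", "superkingdom", "genus"), c(1L, 1L, 2L))
#' lineage(tx, 7L)  # 1 2 7
lineage <- function(tax, id) {
  pos <- .taxPos(tax, id)
  path <- integer(0)
  repeat {
    path <- c(tax@ids[pos], path)
    if (tax@ids[pos] == 1L) break
    pos <- match(tax@parents[pos], tax@ids)
  }
  path
}

#' Ancestor test
#'
#' Is `a` an ancestor of `b`? A taxon is considered its own ancestor, and
#' the root is an ancestor of everything.
#'
#' @param tax a [Taxonomy-class].
#' @param a,b taxon ids present in the tree.
#' @return Logical scalar.
#' @export
isAncestor <- function(tax, a, b) {
  .taxPos(tax, a)
  as.integer(a) %in% lineage(tax, b)
}

#' Nearest valid ancestor
#'
#' Maps a taxon to itself when valid, otherwise to the closest ancestor
#' flagged valid (the root is always a last resort). Identifications on
#' invalid taxa are redirected through this at index-build and profiling
#' time.
#'
#' @param tax a [Taxonomy-class].
#' @param ids integer vector of taxon ids.
#' @return Integer vector of the same length.
#' @export
nearestValidAncestor <- function(tax, ids) {
  vapply(as.integer(ids), function(id) {
    lin <- lineage(tax, id)
    ok <- tax@valid[match(lin, tax@ids)]
    if (any(ok)) lin[max(which(ok))] else 1L
  }, integer(1))
}

#' Snap a taxon to a canonical rank
#'
#' Maps a prediction to the unique ancestor-or-self at the requested
#' canonical rank. Predictions more specific than the rank are mapped up
#' to it; predictions less specific than the rank (no node at that rank on
#' the lineage) are mapped to the root (id 1), i.e. treated as no
#' assignment. Idempotent.
#'
#' @param tax a [Taxonomy-class].
#' @param id a taxon id present in the tree.
#' @param rank a canonical rank name from `tax@rankOrder` (not "no rank").
#' @return A taxon id: the ancestor at `rank`, or 1.
#' @export
snapToRank <- function(tax, id, rank) {
  if (!rank %in% setdiff(tax@rankOrder, "no rank"))
    stop(sprintf("unknown rank: %s", rank))
  lin <- lineage(tax, id)
  at <- lin[tax@ranks[match(lin, tax@ids)] == rank]
  if (length(at)) at[1L] else 1L
}
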