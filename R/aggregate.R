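#' @title Consensus heuristics on a taxon multiset
#'
#' @description Four heuristics that reduce a frequency table of
#' per-peptide identifications to one consensus taxon for a read, trading
#' off specificity (distance from the root) against robustness to false
#' positives:
#'
#' * `aggregateLCA()` - standard lowest common ancestor: the deepest taxon
#'   that is an ancestor of every input taxon. Most conservative.
#' * `aggregateLCAStar()` - LCA after discarding every input taxon that is
#'   a strict ancestor of another input taxon; equivalently the most
#'   specific taxon that is an ancestor or descendant of every input.
#' * `aggregateMRTL()` - maximum root-to-leaf: the input taxon whose
#'   lineage carries the largest count-weighted number of input taxa. The
#'   result is always a member of the input. Most progressive.
#' * `aggregateHybrid()` - greedy root-to-leaf descent: at each node,
#'   descend into the child subtree holding the largest count-weighted
#'   share of the identifications strictly below the current node iff that
#'   share is at least `f`. With `f = 1` this equals LCA*; with `f = 0` it
#'   descends as deep as the identifications reach.
#'
#' Ties (MRTL score ties, equal-mass children in the hybrid descent) are
#' broken deterministically in favour of the smallest taxon id.
#'
#' @param tax a [Taxonomy-class].
#' @param taxa integer vector of taxon ids; repetitions count.
#' @param counts optional positive integer weights parallel to `taxa`
#'   (default: each occurrence counts once).
#' @param f hybrid balance parameter in `[0, 1]`.
#' @return A single consensus taxon id.
#' @name aggregation
#' @examples
#' tx <- taxonomy(c(1L, 2L, 10L, 101L, 102L),
#'                c("root", "Bacteria", "GenusA", "sp1", "sp2"),
#'                c("no rank", "superkingdom", "genus", "species", "species"),
#'                c(1L, 1L, 2L, 10L, 10L))
#' aggregateLCA(tx, c(101L, 102L))       # 10 (their genus)
#' aggregateLCAStar(tx, c(10L, 101L))    # 101 (ancestor discarded)
#' aggregateMRTL(tx, c(10L, 101L))       # 101 (2 lineage hits vs 1)
#' aggregateHybrid(tx, c(101L, 102L), f = 0.75)  # 10 (1/2 < 0.75)
NULL

# collapse (taxa, counts) to distinct ids with summed weights
.multiset <- function(tax, taxa, counts) {
  taxa <- as.integer(taxa)
  if (length(taxa) == 0L) stop("empty taxon multiset")
  .taxPos(tax, unique(taxa))
  if (is.null(counts)) counts <- rep.int(1L, length(taxa))
  stopifnot(length(counts) == length(taxa), all(counts > 0))
  w <- tapply(as.numeric(counts), taxa, sum)
  list(ids = as.integer(names(w)), w = as.numeric(w))
}

# longest common prefix of a list of lineages -> last shared element
.lcaOfLineages <- function(lins) {
  ref <- lins[[1L]]
  k <- length(ref)
  for (l in lins[-1L]) {
    n <- min(k, length(l))
    same <- ref[seq_len(n)] == l[seq_len(n)]
    k <- if (all(same)) n else which.min(same) - 1L
  }
  ref[k]
}

#' @rdname aggregation
#' @export
aggregateLCA <- function(tax, taxa, counts = NULL) {
  ms <- .multiset(tax, taxa, counts)
  .lcaOfLineages(lapply(ms$ids, lineage, tax = tax))
}

#' @rdname aggregation
#' @export
aggregateLCAStar <- function(tax, taxa, counts = NULL) {
  ms <- .multiset(tax, taxa, counts)
  lins <- lapply(ms$ids, lineage, tax = tax)
  # discard members that are strict ancestors of another member
  keep <- vapply(seq_along(ms$ids), function(i) {
    !any(vapply(seq_along(ms$ids), function(j) {
      j != i && ms$ids[i] %in% lins[[j]][-length(lins[[j]])]
    }, logical(1)))
  }, logical(1))
  .lcaOfLineages(lins[keep])
}

#' @rdname aggregation
#' @export
aggregateMRTL <- function(tax, taxa, counts = NULL) {
  ms <- .multiset(tax, taxa, counts)
  lins <- lapply(ms$ids, lineage, tax = tax)
  score <- vapply(lins, function(l) sum(ms$w[ms$ids %in% l]), numeric(1))
  cand <- ms$ids[score == max(score)]
  min(cand)
}

#' @rdname aggregation
#' @export
aggregateHybrid <- function(tax, taxa, counts = NULL, f) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("hybrid parameter f must be a single number in [0, 1]")
  ms <- .multiset(tax, taxa, counts)
  lins <- lapply(ms$ids, lineage, tax = tax)
  cur <- 1L
  repeat {
    # members strictly below cur, and the child of cur each passes through
    below <- vapply(seq_along(ms$ids), function(i) {
      l <- lins[[i]]
      p <- match(cur, l)
      if (is.na(p) || p == length(l)) NA_integer_ else l[p + 1L]
    }, integer(1))
    mass <- tapply(ms$w[!is.na(below)], below[!is.na(below)], sum)
    if (length(mass) == 0L) break
    total <- sum(mass)
    best <- as.integer(names(mass)[order(-mass, as.integer(names(mass)))[1L]])
    if (mass[as.character(best)] / total >= f) cur <- best else break
  }
  cur
}
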