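#' @import methods
NULL

#' Canonical NCBI-style rank order
#'
#' The ordered list of canonical taxonomic ranks, from root-most to
#' leaf-most, used by default for rank snapping and rank-filtered
#' reporting. "no rank" nodes are allowed anywhere in a lineage and are
#' never snap targets.
#'
#' @return Character vector of rank names, root-most first.
#' @export
#' @examples
#' head(canonicalRanks())
canonicalRanks <- function() {
  c("no rank",
    "superkingdom", "kingdom", "subkingdom",
    "superphylum", "phylum", "subphylum",
    "superclass", "class", "subclass", "infraclass",
    "superorder", "order", "suborder", "infraorder", "parvorder",
    "superfamily", "family", "subfamily",
    "tribe", "subtribe",
    "genus", "subgenus",
    "species group", "species subgroup", "species",
    "subspecies", "varietas", "forma")
}

#' Taxonomy: an NCBI-style taxonomic tree
#'
#' Holds a rooted taxonomy as parallel per-node vectors plus the ordered
#' list of canonical ranks. The root has id 1 and is its own parent; every
#' other node's parent must resolve within the tree and parent chains must
#' terminate at the root. Nodes flagged invalid are retained in the tree
#' but identifications landing on them are redirected to their nearest
#' valid ancestor (see [nearestValidAncestor()]).
#'
#' @slot ids integer taxon identifiers (unique, positive).
#' @slot names character scientific names.
#' @slot ranks character rank of each node ("no rank" allowed).
#' @slot parents integer parent identifier of each node.
#' @slot valid logical validity flag per node.
#' @slot rankOrder character canonical rank order, root-most first.
#'
#' @seealso [readTaxonomy()], [lineage()], [snapToRank()],
#'   [aggregateLCAStar()]
#' @export
setClass("Taxonomy",
  representation(
    ids = "integer",
    names = "character",
    ranks = "character",
    parents = "integer",
    valid = "logical",
    rankOrder = "character"
  )
)

setValidity("Taxonomy", function(object) {
  n <- length(object@ids)
  if (length(object@names) != n || length(object@ranks) != n ||
      length(object@parents) != n || length(object@valid) != n)
    return("per-node slots must have equal length")
  if (n == 0L) return("taxonomy must contain at least the root")
  if (anyDuplicated(object@ids)) return("taxon ids must be unique")
  if (any(object@ids < 1L)) return("taxon ids must be positive")
  if (!1L %in% object@ids) return("root (id 1) missing")
  root <- match(1L, object@ids)
  if (object@parents[root] != 1L) return("root must be its own parent")
  orphan <- !(object@parents %in% object@ids)
  if (any(orphan))
    return(sprintf("parent id %d of taxon %d not in taxonomy",
                   object@parents[which(orphan)[1L]],
                   object@ids[which(orphan)[1L]]))
  # parent chains must reach the root (no cycles)
  pos <- match(object@parents, object@ids)
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i
    j <- i
    repeat {
      j <- pos[j]
      if (!is.na(depth[j])) break
      if (j %in% chain) return(sprintf("cycle through taxon %d", object@ids[j]))
      chain <- c(chain, j)
    }
    depth[chain] <- depth[j] + rev(seq_along(chain))
  }
  if (!all(object@ranks %in% c(object@rankOrder, "no rank")))
    return("node rank not in rank order")
  TRUE
})

#' @describeIn Taxonomy Number of taxa in the tree.
#' @param x,object a `Taxonomy`.
#' @export
setMethod("length", "Taxonomy", function(x) length(x@ids))

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy with %d taxa (%d valid), %d canonical ranks\n",
              length(object@ids), sum(object@valid),
              length(setdiff(object@rankOrder, "no rank"))))
  shown <- table(factor(object@ranks,
                        levels = intersect(object@rankOrder, object@ranks)))
  shown <- shown[shown > 0]
  cat("  ranks:",
      paste(sprintf("%s (%d)", names(shown), shown), collapse = ", "), "\n")
})

#' PeptideIndex: exact-match ordered map from peptide to consensus taxon
#'
#' Maps every peptide extracted from a reference proteome to the LCA*
#' (modified lowest common ancestor) of the distinct taxa of all reference
#' proteins containing that peptide. Keys are unique and, in serialized
#' form, lexicographically ordered (byte order); lookups are exact string
#' matches and an absent key means the peptide is unidentified.
#'
#' @slot peptides character, the unique peptide keys in byte-sorted order.
#' @slot taxa integer consensus taxon per peptide.
#' @slot meta list describing how the index was built: `mode` ("kmer" or
#'   "tryptic"), `k`, `pattern`, `minLen`, `maxLen`, and
#'   `taxonomyChecksum` of the taxonomy used.
#'
#' @seealso [buildIndex()], [lookupPeptides()], [writeIndex()],
#'   [readIndex()]
#' @export
setClass("PeptideIndex",
  representation(
    peptides = "character",
    taxa = "integer",
    meta = "list"
  )
)

setValidity("PeptideIndex", function(object) {
  if (length(object@peptides) != length(object@taxa))
    return("peptides and taxa must be parallel")
  if (anyDuplicated(object@peptides)) return("peptide keys must be unique")
  if (!identical(object@peptides, sort(object@peptides, method = "radix")))
    return("peptide keys must be in lexicographic (byte) order")
  if (length(object@taxa) && any(object@taxa < 1L, na.rm = TRUE))
    return("taxon ids must be positive")
  needed <- c("mode", "k", "pattern", "minLen", "maxLen", "taxonomyChecksum")
  if (!all(needed %in% names(object@meta)))
    return(paste("meta must contain:", paste(needed, collapse = ", ")))
  TRUE
})

#' @describeIn PeptideIndex Number of peptide entries.
#' @param x,object a `PeptideIndex`.
#' @export
setMethod("length", "PeptideIndex", function(x) length(x@peptides))

setMethod("show", "PeptideIndex", function(object) {
  m <- object@meta
  what <- if (identical(m$mode, "kmer")) sprintf("%d-mer", m$k)
          else sprintf("tryptic (len %d-%d)", m$minLen, m$maxLen)
  cat(sprintf("PeptideIndex: %d %s peptides -> LCA* taxa\n",
              length(object@peptides), what))
  if (length(object@peptides)) {
    i <- seq_len(min(3L, length(object@peptides)))
    cat(paste(sprintf("  %s -> %d", object@peptides[i], object@taxa[i]),
              collapse = "\n"), "\n")
  }
})

#' PipelineConfig: all tunables of the read-profiling pipeline
#'
#' @slot translation "sixframe" (translate the read in all six reading
#'   frames) or "predicted" (adopt externally predicted protein fragments).
#' @slot table character NCBI translation table identifier (default "11").
#' @slot fragmentation list with `mode` ("kmer"/"tryptic"), `k`,
#'   `pattern`, `minLen`, `maxLen` (length bounds applied to tryptic
#'   peptides at query time).
#' @slot filters list with `minHits` (low-frequency filter; 1 = off),
#'   `seedMin` (seed-and-extend minimum seed size s; 0 = off) and `gapMax`
#'   (maximum bridged gap g).
#' @slot aggregation list with `method` ("lca", "lca_star", "mrtl",
#'   "hybrid") and `f` (hybrid only, in [0,1]).
#' @slot name preset name, or "" for a custom configuration.
#'
#' @seealso [pipelineConfig()], [preset()], [profileReads()]
#' @export
setClass("PipelineConfig",
  representation(
    translation = "character",
    table = "character",
    fragmentation = "list",
    filters = "list",
    aggregation = "list",
    name = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  if (!object@translation %in% c("sixframe", "predicted"))
    return("translation must be 'sixframe' or 'predicted'")
  fr <- object@fragmentation
  if (!identical(sort(names(fr)),
                 sort(c("mode", "k", "pattern", "minLen", "maxLen"))))
    return("fragmentation must have mode, k, pattern, minLen, maxLen")
  if (!fr$mode %in% c("kmer", "tryptic"))
    return("fragmentation mode must be 'kmer' or 'tryptic'")
  if (fr$mode == "kmer" && (!is.numeric(fr$k) || fr$k < 1))
    return("k must be a positive integer")
  if (fr$mode == "tryptic" && fr$minLen > fr$maxLen)
    return("minLen must not exceed maxLen")
  fl <- object@filters
  if (!all(c("minHits", "seedMin", "gapMax") %in% names(fl)))
    return("filters must have minHits, seedMin, gapMax")
  if (fl$minHits < 1) return("minHits must be >= 1")
  if (fl$seedMin != 0 && fl$seedMin < 2)
    return("seedMin must be 0 (off) or >= 2")
  if (fl$gapMax < 0) return("gapMax must be >= 0")
  ag <- object@aggregation
  if (!ag$method %in% c("lca", "lca_star", "mrtl", "hybrid"))
    return("aggregation method must be lca, lca_star, mrtl or hybrid")
  if (ag$method == "hybrid" && (ag$f < 0 || ag$f > 1))
    return("hybrid f must be in [0, 1]")
  TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  fr <- object@fragmentation
  frag <- if (fr$mode == "kmer") sprintf("%d-mers", fr$k)
          else sprintf("tryptic %d-%d aa", fr$minLen, fr$maxLen)
  fl <- object@filters
  se <- if (fl$seedMin >= 2)
    sprintf("seed-and-extend s=%d g=%d", fl$seedMin, fl$gapMax) else "no seed-and-extend"
  ag <- object@aggregation
  agg <- if (ag$method == "hybrid") sprintf("hybrid f=%.2f", ag$f) else ag$method
  cat(sprintf("PipelineConfig%s: %s | table %s | %s | min hits %d | %s | %s\n",
              if (nzchar(object@name)) sprintf(" '%s'", object@name) else "",
              object@translation, object@table, frag, fl$minHits, se, agg))
})
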