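#' Construct a pipeline configuration
#'
#' Assembles all tunables of the read profiler. See
#' [PipelineConfig-class] for the meaning of each group and [preset()]
#' for the six preconfigured pipelines.
#'
#' @param translation `"sixframe"` or `"predicted"`.
#' @param table NCBI translation table identifier.
#' @param fragmentation from [fragmentationParams()].
#' @param minHits low-frequency filter: minimum per-read taxon hits
#'   (1 = no filtering).
#' @param seedMin seed-and-extend minimum seed size s (0 = filter off,
#'   otherwise >= 2).
#' @param gapMax seed-and-extend maximum bridged gap g.
#' @param method read-level consensus heuristic: `"lca"`, `"lca_star"`,
#'   `"mrtl"` or `"hybrid"`.
#' @param f hybrid balance parameter in `[0, 1]`.
#' @param name optional preset name.
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(translation = c("sixframe", "predicted"),
                           table = "11",
                           fragmentation = fragmentationParams(),
                           minHits = 1L, seedMin = 0L, gapMax = 0L,
                           method = c("lca_star", "lca", "mrtl", "hybrid"),
                           f = 1, name = "") {
  new("PipelineConfig",
      translation = match.arg(translation),
      table = as.character(table),
      fragmentation = fragmentation,
      filters = list(minHits = as.integer(minHits),
                     seedMin = as.integer(seedMin),
                     gapMax = as.integer(gapMax)),
      aggregation = list(method = match.arg(method), f = f),
      name = name)
}

#' Preconfigured pipelines
#'
#' The six pipeline configurations selected for their accuracy trade-offs,
#' ranging from maximum precision to maximum sensitivity. The tryptic and
#' "max precision" presets expect externally predicted protein fragments
#' (a short-read gene predictor's output, see
#' [readPredictedFragments()]); the others use six-frame translation.
#'
#' * `tryptic-precision`: predicted genes, tryptic peptides of length
#'   5-45, minimum 2 taxon hits, MRTL.
#' * `tryptic-sensitivity`: predicted genes, tryptic peptides of length
#'   9-45, no low-frequency filtering, MRTL.
#' * `max-precision`: predicted genes, 9-mers, minimum 5 taxon hits,
#'   seed-and-extend s=2 g=2, hybrid f=0.75.
#' * `high-precision`: six-frame translation, 9-mers, minimum 4 taxon
#'   hits, seed-and-extend s=3 g=4, hybrid f=0.5.
#' * `high-sensitivity`: six-frame translation, 9-mers, no low-frequency
#'   filtering, seed-and-extend s=3 g=0, MRTL.
#' * `max-sensitivity`: six-frame translation, 9-mers, no low-frequency
#'   filtering, seed-and-extend s=2 g=0, MRTL.
#'
#' @param name one of the preset names above.
#' @return A [PipelineConfig-class].
#' @export
#' @examples
#' preset("high-precision")
preset <- function(name) {
  tryp <- function(minLen, maxLen)
    fragmentationParams("tryptic", minLen = minLen, maxLen = maxLen)
  switch(name,
    "tryptic-precision" = pipelineConfig("predicted",
      fragmentation = tryp(5L, 45L), minHits = 2L, method = "mrtl",
      name = name),
    "tryptic-sensitivity" = pipelineConfig("predicted",
      fragmentation = tryp(9L, 45L), minHits = 1L, method = "mrtl",
      name = name),
    "max-precision" = pipelineConfig("predicted",
      fragmentation = fragmentationParams("kmer", k = 9L),
      minHits = 5L, seedMin = 2L, gapMax = 2L,
      method = "hybrid", f = 0.75, name = name),
    "high-precision" = pipelineConfig("sixframe",
      fragmentation = fragmentationParams("kmer", k = 9L),
      minHits = 4L, seedMin = 3L, gapMax = 4L,
      method = "hybrid", f = 0.5, name = name),
    "high-sensitivity" = pipelineConfig("sixframe",
      fragmentation = fragmentationParams("kmer", k = 9L),
      minHits = 1L, seedMin = 3L, gapMax = 0L,
      method = "mrtl", name = name),
    "max-sensitivity" = pipelineConfig("sixframe",
      fragmentation = fragmentationParams("kmer", k = 9L),
      minHits = 1L, seedMin = 2L, gapMax = 0L,
      method = "mrtl", name = name),
    stop(sprintf("unknown preset: %s", name)))
}

# stop unless the query-time fragmentation can be served by the index
.checkIndexCompat <- function(index, params) {
  m <- index@meta
  if (!identical(m$mode, params$mode))
    stop(sprintf("fragmentation mode '%s' does not match index mode '%s'",
                 params$mode, m$mode))
  if (params$mode == "kmer" && !isTRUE(m$k == params$k))
    stop(sprintf("k = %d does not match index k = %d", params$k, m$k))
  if (params$mode == "tryptic" && !identical(m$pattern, params$pattern))
    stop("tryptic split pattern does not match the pattern the index was built with")
  invisible(TRUE)
}

#' Look up a peptide list in the index, preserving adjacency structure
#'
#' Produces the per-read identification track: one item per peptide, in
#' emission order, carrying the peptide's consensus taxon or `NA` when it
#' has no exact match. `segment` marks stretches of genuinely neighboring
#' peptides (one translated fragment); adjacency — and therefore
#' seed-and-extend — never crosses a segment boundary.
#'
#' @param index a [PeptideIndex-class].
#' @param peptides character vector in emission order.
#' @param segments integer vector parallel to `peptides`; equal values =
#'   same fragment.
#' @param params optional fragmentation parameters to validate against
#'   the index metadata.
#' @return data.frame with columns `peptide`, `taxon` (integer, `NA` =
#'   unidentified) and `segment`.
#' @export
profilePeptides <- function(index, peptides,
                            segments = rep(1L, length(peptides)),
                            params = NULL) {
  if (!is.null(params)) .checkIndexCompat(index, params)
  stopifnot(length(segments) == length(peptides))
  data.frame(peptide = as.character(peptides),
             taxon = lookupPeptides(index, peptides),
             segment = as.integer(segments),
             stringsAsFactors = FALSE)
}

#' Seed-and-extend filtering of an identification track
#'
#' Exploits local conservation of identifications along a translated
#' fragment. A seed is a run of at least `s` consecutive items (not
#' crossing a segment boundary) carrying the same taxon. Each seed is
#' extended in both directions across neighboring identified items and
#' seeds, bridging runs of unidentified items of length at most `g`;
#' everything outside every extended seed is dropped. Relative order is
#' preserved. Raising `s` never retains more items; raising `g` never
#' retains fewer.
#'
#' @param track data.frame from [profilePeptides()].
#' @param s minimum seed size (>= 2).
#' @param g maximum bridged gap (>= 0).
#' @return The filtered track (subset of the input rows, same order).
#' @export
#' @examples
#' tr <- data.frame(peptide = letters[1:7],
#'                  taxon = c(5L, 5L, 5L, NA, 9L, 5L, 5L),
#'                  segment = 1L)
#' seedExtendFilter(tr, s = 3, g = 1)  # retains all seven positions
seedExtendFilter <- function(track, s, g) {
  stopifnot(s >= 2L, g >= 0L)
  keep <- logical(nrow(track))
  for (seg in unique(track$segment)) {
    idx <- which(track$segment == seg)
    t <- track$taxon[idx]
    r <- rle(ifelse(is.na(t), -1L, t))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ident <- which(r$values != -1L)
    if (!length(ident)) next
    seed <- r$values != -1L & r$lengths >= s
    # walk identified runs; link consecutive ones when the gap between
    # them (an unidentified run, or nothing) has length <= g
    comp <- integer(length(ident))
    comp[1L] <- 1L
    if (length(ident) > 1L) for (j in 2:length(ident)) {
      gap <- starts[ident[j]] - ends[ident[j - 1L]] - 1L
      comp[j] <- if (gap <= g) comp[j - 1L] else comp[j - 1L] + 1L
    }
    for (cc in unique(comp)) {
      runs <- ident[comp == cc]
      if (!any(seed[runs])) next
      keep[idx[starts[runs[1L]]:ends[runs[length(runs)]]]] <- TRUE
    }
  }
  track[keep, , drop = FALSE]
}

#' Drop low-frequency identifications
#'
#' True identifications along the correct lineage recur within a read;
#' false positives scatter. Taxa observed fewer than `minHits` times in
#' the read are removed. `minHits = 1` is the identity.
#'
#' @param counts named integer vector (names = taxon ids) or `table` of
#'   per-read identification counts.
#' @param minHits minimum count to survive (>= 1).
#' @return Named integer vector of surviving counts (possibly empty).
#' @export
lowFrequencyFilter <- function(counts, minHits) {
  stopifnot(minHits >= 1L)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out >= minHits]
}

.aggregate <- function(tax, ids, counts, agg) {
  switch(agg$method,
    lca = aggregateLCA(tax, ids, counts),
    lca_star = aggregateLCAStar(tax, ids, counts),
    mrtl = aggregateMRTL(tax, ids, counts),
    hybrid = aggregateHybrid(tax, ids, counts, f = agg$f))
}

# consensus for one read from its (already filtered) track
.consensusFromTrack <- function(track, tax, filters, agg) {
  if (nrow(track) && filters$seedMin >= 2L)
    track <- seedExtendFilter(track, filters$seedMin, filters$gapMax)
  t <- track$taxon[!is.na(track$taxon)]
  if (!length(t)) return(1L)
  counts <- table(t)
  counts <- lowFrequencyFilter(counts, filters$minHits)
  if (!length(counts)) return(1L)
  .aggregate(tax, as.integer(names(counts)), as.integer(counts), agg)
}

#' Profile reads to one consensus taxon each
#'
#' Runs the full per-read pipeline: translation (six reading frames, or
#' adoption of predicted fragments), peptide fragmentation (with tryptic
#' length filtering), exact index lookup, seed-and-extend filtering,
#' low-frequency filtering, and consensus aggregation. Reads with no
#' surviving identification are assigned the root (taxon 1). For
#' paired-end data both mates' identification tracks are concatenated —
#' with a break between them — before filtering, since both reads come
#' from the same organism.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads; for
#'   `translation = "predicted"` this may be `NULL` if `predicted` covers
#'   all reads, but names of `reads` still define the output order when
#'   given.
#' @param index a [PeptideIndex-class] (its fragmentation metadata must
#'   match the configuration).
#' @param tax a [Taxonomy-class].
#' @param config a [PipelineConfig-class].
#' @param mates optional named character vector of second mates; names
#'   must match `reads` (the pair is reported under the first mate's id).
#' @param predicted data.frame from [readPredictedFragments()], required
#'   when `config@translation == "predicted"`.
#' @return data.frame with columns `read_id` and `taxon_id` (1 =
#'   unassigned), one row per read (pair), in input order.
#' @export
profileReads <- function(reads, index, tax, config, mates = NULL,
                         predicted = NULL) {
  validObject(config)
  .checkIndexCompat(index, config@fragmentation)
  if (config@translation == "predicted") {
    if (is.null(predicted))
      stop("config uses predicted fragments: supply `predicted`")
    frags <- predicted
    ids <- if (!is.null(reads) && !is.null(names(reads))) names(reads)
           else unique(frags$read_id)
  } else {
    if (is.null(reads)) stop("six-frame translation requires `reads`")
    reads <- as.character(Biostrings::DNAStringSet(reads))
    ids <- names(reads)
    if (is.null(ids)) stop("reads must be named by read id")
    frags <- sixFrameTranslate(reads, table = config@table)
    if (!is.null(mates)) {
      if (is.null(names(mates)) || !all(names(mates) %in% ids))
        stop("mate names must match first-mate read ids")
      f2 <- sixFrameTranslate(as.character(Biostrings::DNAStringSet(mates)),
                              table = config@table)
      f2$frame <- paste0("mate2", f2$frame)
      frags <- rbind(frags, f2)
    }
  }
  params <- config@fragmentation
  if (nrow(frags)) {
    peps <- lapply(frags$sequence, .fragment, params = params)
    if (params$mode == "tryptic")
      peps <- lapply(peps, filterPeptideLength,
                     minLen = params$minLen, maxLen = params$maxLen)
    np <- lengths(peps)
    all <- data.frame(
      read_id = rep(frags$read_id, np),
      segment = rep(seq_len(nrow(frags)), np),  # one segment per fragment
      peptide = unlist(peps, use.names = FALSE),
      stringsAsFactors = FALSE)
    all$taxon <- lookupPeptides(index, all$peptide)
    tracks <- split(all[c("peptide", "taxon", "segment")],
                    factor(all$read_id, levels = ids))
  } else {
    tracks <- rep(list(data.frame(peptide = character(0),
                                  taxon = integer(0),
                                  segment = integer(0))), length(ids))
    names(tracks) <- ids
  }
  consensus <- vapply(ids, function(id) {
    tr <- tracks[[id]]
    if (is.null(tr)) return(1L)
    .consensusFromTrack(tr, tax, config@filters, config@aggregation)
  }, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = ids, taxon_id = consensus, stringsAsFactors = FALSE)
}

#' Write / read per-read profiles
#'
#' FASTA-like output: per read (pair) a `>read_id` header line followed
#' by one line with the consensus taxon id.
#'
#' @param profiles data.frame with `read_id`, `taxon_id`.
#' @param path output path (a `.gz` suffix compresses transparently).
#' @return `path`, invisibly (`writeProfiles`); the profiles data.frame
#'   (`readProfiles`).
#' @export
writeProfiles <- function(profiles, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wb")
         else file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", profiles$read_id, "\n", profiles$taxon_id),
             con, sep = "\n")
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  data.frame(read_id = sub("^>", "", lines[hdr]),
             taxon_id = as.integer(lines[!hdr]),
             stringsAsFactors = FALSE)
}
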