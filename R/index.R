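#' Checksum of a taxonomy
#'
#' Small deterministic polynomial hash over the serialized node table,
#' recorded in index metadata so that an index can warn when queried
#' against a different taxonomy than it was built with.
#'
#' @param tax a [Taxonomy-class].
#' @return A single integer-valued double below 2^31.
#' @export
taxonomyChecksum <- function(tax) {
  s <- paste(tax@ids, tax@ranks, tax@parents, tax@valid,
             sep = "|", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Read an annotated reference proteome FASTA
#'
#' Header convention: `>protein_id taxid=<int> ...` — the first token is
#' the protein id and a `taxid=` key/value anywhere in the description
#' carries the taxonomic annotation.
#'
#' @param path protein FASTA (gzip accepted).
#' @return data.frame with columns `id`, `taxon_id`, `sequence`.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- sub("\\s.*$", "", hdr)
  m <- regmatches(hdr, regexpr("taxid=\\d+", hdr))
  tx <- rep(NA_integer_, length(hdr))
  has <- grepl("taxid=\\d+", hdr)
  tx[has] <- as.integer(sub("taxid=", "", m))
  if (anyNA(tx))
    stop(sprintf("record '%s' carries no taxid= annotation", id[is.na(tx)][1L]))
  data.frame(id = unname(id), taxon_id = tx,
             sequence = unname(as.character(aa)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an annotated reference proteome FASTA
#'
#' @param proteins data.frame with `id`, `taxon_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- sprintf("%s taxid=%d", proteins$id, proteins$taxon_id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build a peptide-to-LCA* index from a reference proteome
#'
#' Fragments every reference protein under the given parameters (tryptic
#' peptides are filtered to the build length bounds) and maps each
#' distinct peptide to the LCA* of the distinct taxa of all proteins
#' containing it — the most specific taxon contradicting none of them. A
#' peptide occurring many times within one species still counts that
#' species once. Identifications on taxa flagged invalid are redirected
#' to their nearest valid ancestor first.
#'
#' @param proteins data.frame with `id`, `taxon_id`, `sequence` (see
#'   [readProteinFasta()]).
#' @param params fragmentation parameters from [fragmentationParams()].
#' @param tax the [Taxonomy-class] the annotations live in.
#' @return A [PeptideIndex-class]; entries are independent of the input
#'   protein order.
#' @export
buildIndex <- function(proteins, params, tax) {
  stopifnot(nrow(proteins) > 0L)
  unknown <- !(proteins$taxon_id %in% tax@ids)
  if (any(unknown))
    stop(sprintf("protein '%s' has unknown taxon id %d",
                 proteins$id[unknown][1L], proteins$taxon_id[unknown][1L]))
  taxon <- nearestValidAncestor(tax, proteins$taxon_id)
  peps <- lapply(proteins$sequence, .fragment, params = params)
  if (params$mode == "tryptic")
    peps <- lapply(peps, filterPeptideLength,
                   minLen = params$minLen, maxLen = params$maxLen)
  pair <- unique(data.frame(pep = unlist(peps, use.names = FALSE),
                            taxon = rep(taxon, lengths(peps)),
                            stringsAsFactors = FALSE))
  if (nrow(pair) == 0L) stop("no peptides produced from the proteome")
  keys <- sort(unique(pair$pep), method = "radix")
  groups <- split(pair$taxon, factor(pair$pep, levels = keys))
  vals <- vapply(groups, function(ts) {
    if (length(ts) == 1L) ts else aggregateLCAStar(tax, ts)
  }, integer(1), USE.NAMES = FALSE)
  meta <- list(mode = params$mode,
               k = if (params$mode == "kmer") params$k else NA_integer_,
               pattern = if (params$mode == "tryptic") params$pattern
                         else NA_character_,
               minLen = if (params$mode == "tryptic") params$minLen
                        else NA_integer_,
               maxLen = if (params$mode == "tryptic") params$maxLen
                        else NA_integer_,
               taxonomyChecksum = taxonomyChecksum(tax))
  new("PeptideIndex", peptides = keys, taxa = vals, meta = meta)
}

#' Exact-match peptide lookup
#'
#' @param index a [PeptideIndex-class].
#' @param peptides character vector of peptides.
#' @return Integer vector of consensus taxon ids, `NA` where a peptide
#'   has no exact match (unidentified).
#' @export
lookupPeptides <- function(index, peptides) {
  index@taxa[match(peptides, index@peptides)]
}

.META_FIELDS <- c(mode = "mode", k = "k", pattern = "pattern",
                  minLen = "min_len", maxLen = "max_len",
                  taxonomyChecksum = "taxonomy_checksum")

#' Serialize a peptide index
#'
#' Writes the index as lexicographically sorted, LF-terminated, ASCII TSV
#' (`peptide<TAB>taxon_id`), preceded by a commented metadata header.
#' Two builds from the same inputs produce byte-identical files.
#'
#' @param index a [PeptideIndex-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIndex <- function(index, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  m <- index@meta
  hdr <- c("# peptax-index 1",
           vapply(names(.META_FIELDS), function(f) {
             v <- m[[f]]
             sprintf("# %s\t%s", .META_FIELDS[[f]],
                     if (is.na(v)) "-" else as.character(v))
           }, character(1)))
  writeLines(c(hdr, sprintf("%s\t%d", index@peptides, index@taxa)),
             con, sep = "\n")
  invisible(path)
}

#' Load a serialized peptide index
#'
#' Validates the sort order and key uniqueness of the entries; when a
#' taxonomy is supplied, a checksum mismatch with the build-time taxonomy
#' raises a compatibility warning.
#'
#' @param path a file written by [writeIndex()].
#' @param tax optional [Taxonomy-class] to check compatibility against.
#' @return A [PeptideIndex-class]; `readIndex(writeIndex(x))` has
#'   identical entries and metadata.
#' @export
readIndex <- function(path, tax = NULL) {
  lines <- readLines(path)
  isMeta <- grepl("^# ", lines) | lines == "#"
  nMeta <- if (any(!isMeta)) which(!isMeta)[1L] - 1L else length(lines)
  if (nMeta < 1L || !identical(lines[1L], "# peptax-index 1"))
    stop("not a peptide index file (missing header)")
  meta <- list(mode = NA_character_, k = NA_integer_,
               pattern = NA_character_, minLen = NA_integer_,
               maxLen = NA_integer_, taxonomyChecksum = NA_real_)
  for (h in lines[2:nMeta]) {
    kv <- strsplit(sub("^# ", "", h), "\t", fixed = TRUE)[[1L]]
    slot <- names(.META_FIELDS)[.META_FIELDS == kv[1L]]
    if (length(slot) != 1L || length(kv) != 2L) next
    if (kv[2L] != "-")
      meta[[slot]] <- switch(slot,
        mode = , pattern = kv[2L],
        k = , minLen = , maxLen = as.integer(kv[2L]),
        taxonomyChecksum = as.numeric(kv[2L]))
  }
  body <- lines[seq_len(length(lines) - nMeta) + nMeta]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop(sprintf("malformed index line %d",
                 nMeta + which(lengths(parts) != 2L)[1L]))
  keys <- vapply(parts, `[`, character(1), 1L)
  vals <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(vals)) stop("malformed index line: non-integer taxon id")
  if (anyDuplicated(keys) ||
      !identical(keys, sort(keys, method = "radix")))
    stop("index entries are not unique and lexicographically sorted")
  if (!is.null(tax) && !is.na(meta$taxonomyChecksum) &&
      meta$taxonomyChecksum != taxonomyChecksum(tax))
    warning("index was built against a different taxonomy (checksum mismatch)")
  new("PeptideIndex", peptides = keys, taxa = vals, meta = meta)
}

# byte-order comparison of two ASCII strings: -1, 0, or 1
.cmpBytes <- function(a, b) {
  ra <- as.integer(charToRaw(a)); rb <- as.integer(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n > 0L) {
    d <- which(ra[seq_len(n)] != rb[seq_len(n)])
    if (length(d)) return(sign(ra[d[1L]] - rb[d[1L]]))
  }
  sign(length(ra) - length(rb))
}

#' On-disk peptide lookup by binary search
#'
#' Queries a serialized index file directly, without loading it into
#' memory, by binary search over the byte-sorted entries. Behaviourally
#' identical to [lookupPeptides()] on the loaded index; slower per query
#' but with negligible memory use.
#'
#' @param path a file written by [writeIndex()].
#' @param peptides character vector of peptides.
#' @return Integer vector of taxon ids, `NA` where absent.
#' @export
lookupPeptidesDisk <- function(path, peptides) {
  size <- file.size(path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  # data starts at the first line not beginning with '#'
  seek(con, 0)
  buf <- raw(0)
  start <- NA_real_
  repeat {
    more <- readBin(con, "raw", n = 4096L)
    if (length(more)) buf <- c(buf, more)
    starts <- c(0, which(buf == as.raw(10L)))  # byte offsets of line starts
    starts <- starts[starts < length(buf)]
    hit <- starts[buf[starts + 1L] != charToRaw("#")]
    if (length(hit)) { start <- hit[1L]; break }
    if (!length(more)) stop("index file contains no entries")
  }
  # read the first full line beginning at or after byte `pos`
  lineAt <- function(pos, atStart) {
    seek(con, pos)
    buf <- raw(0)
    while (length(buf) < 2L * 4096L && pos + length(buf) < size)
      buf <- c(buf, readBin(con, "raw", n = 4096L))
    txt <- strsplit(rawToChar(buf), "\n", fixed = TRUE)[[1L]]
    if (!atStart) txt <- txt[-1L]  # drop partial first line
    if (!length(txt)) return(NULL)
    txt[1L]
  }
  searchOne <- function(key) {
    lo <- start; hi <- size
    repeat {
      if (hi - lo <= 4096L) {
        seek(con, lo)
        buf <- readBin(con, "raw", n = as.integer(size - lo))
        txt <- strsplit(rawToChar(buf), "\n", fixed = TRUE)[[1L]]
        if (lo != start) txt <- txt[-1L]
        kv <- strsplit(txt, "\t", fixed = TRUE)
        for (p in kv)
          if (length(p) == 2L && p[1L] == key) return(as.integer(p[2L]))
        return(NA_integer_)
      }
      mid <- floor((lo + hi) / 2)
      ln <- lineAt(mid, atStart = FALSE)
      if (is.null(ln)) { hi <- mid; next }
      k <- strsplit(ln, "\t", fixed = TRUE)[[1L]][1L]
      if (.cmpBytes(k, key) > 0L) hi <- mid else lo <- mid
    }
  }
  vapply(peptides, searchOne, integer(1), USE.NAMES = FALSE)
}
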