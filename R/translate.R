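#' @importFrom Biostrings DNAStringSet AAStringSet BStringSet
#'   reverseComplement translate getGeneticCode readDNAStringSet
#'   readAAStringSet writeXStringSet subseq width
NULL

.geneticCode <- function(table) {
  tryCatch(Biostrings::getGeneticCode(as.character(table)),
           error = function(e)
             stop(sprintf("unknown translation table: %s", table)))
}

#' Translate one reading frame of a DNA sequence
#'
#' Translates `dna` in a single reading frame with an NCBI genetic-code
#' table. Frames +1/+2/+3 start at bases 1/2/3 of the forward strand;
#' frame -k is frame +k of the reverse complement. Stop codons are
#' rendered as `*`; codons containing an ambiguous base (e.g. N) are
#' rendered as `X`; a trailing partial codon is dropped.
#'
#' @param dna a single DNA string over `{A,C,G,T,N}`.
#' @param frame one of `1, 2, 3, -1, -2, -3`.
#' @param table NCBI translation table identifier (default `"11"`,
#'   bacterial/archaeal).
#' @return An amino-acid string, possibly containing `*` and `X`; `""` if
#'   fewer than 3 bases remain in the frame.
#' @export
#' @examples
#' translateFrame("ATGAAATAG", 1)   # "MK*"
#' translateFrame("ATGAAA", 2)      # "*"  (reads TGA AA.)
translateFrame <- function(dna, frame, table = "11") {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  gc <- .geneticCode(table)
  x <- Biostrings::DNAStringSet(toupper(dna))
  if (frame < 0) x <- Biostrings::reverseComplement(x)
  off <- abs(frame) - 1L
  n <- Biostrings::width(x) - off
  if (n < 3L) return("")
  x <- Biostrings::subseq(x, start = off + 1L, width = 3L * (n %/% 3L))
  as.character(Biostrings::translate(x, genetic.code = gc,
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

.FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

# split translations at stop symbols, dropping empty pieces
.stopSplit <- function(aa) {
  pieces <- strsplit(aa, "*", fixed = TRUE)
  lapply(pieces, function(p) p[nzchar(p)])
}

#' Six-frame translation of DNA reads into protein fragments
#'
#' Translates every read in all six reading frames and splits each
#' translation at stop codons into protein fragments (coding-region
#' candidates). No read-error correction is attempted: for a read coding
#' in a single frame, at least five of the six frames are noise that
#' downstream exact matching and filtering must remove.
#'
#' @param reads named character vector of DNA sequences, or a
#'   `DNAStringSet`; names are the read ids.
#' @param table NCBI translation table identifier (default `"11"`).
#' @return A data.frame with columns `read_id`, `frame` (one of `+1..+3`,
#'   `-1..-3`), `fragment` (fragment index within the frame) and
#'   `sequence` (stop-free amino-acid string). Reads shorter than 3 bases
#'   contribute no rows (with a warning).
#' @export
#' @examples
#' sixFrameTranslate(c(r1 = "ATGAAATAGATGCCC"))
sixFrameTranslate <- function(reads, table = "11") {
  gc <- .geneticCode(table)
  x <- Biostrings::DNAStringSet(reads)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("read", seq_along(x))
  short <- Biostrings::width(x) < 3L
  if (any(short)) {
    warning(sprintf("%d read(s) shorter than 3 bases produce no fragments",
                    sum(short)))
    x <- x[!short]
    ids <- ids[!short]
  }
  if (length(x) == 0L)
    return(data.frame(read_id = character(0), frame = character(0),
                      fragment = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  rc <- Biostrings::reverseComplement(x)
  out <- vector("list", 6L)
  for (i in 1:3) {
    for (strand in c("+", "-")) {
      y <- if (strand == "+") x else rc
      n <- Biostrings::width(y) - (i - 1L)
      keep <- n >= 3L
      aa <- rep("", length(y))
      if (any(keep)) {
        z <- Biostrings::subseq(y[keep], start = i,
                                width = 3L * (n[keep] %/% 3L))
        aa[keep] <- as.character(
          Biostrings::translate(z, genetic.code = gc,
                                if.fuzzy.codon = "X", no.init.codon = TRUE))
      }
      frags <- .stopSplit(aa)
      nf <- lengths(frags)
      out[[if (strand == "+") i else i + 3L]] <- data.frame(
        read_id = rep(ids, nf),
        frame = rep(paste0(strand, i), sum(nf)),
        fragment = unlist(lapply(nf, seq_len), use.names = FALSE),
        sequence = unlist(frags, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$read_id, ids), match(res$frame, .FRAMES),
            res$fragment), , drop = FALSE]
}

#' Adopt externally predicted protein fragments
#'
#' Reads a protein FASTA produced by a short-read gene predictor and
#' groups the fragments per originating read. The read id is recovered
#' from the first whitespace-delimited header token by stripping a
#' trailing `_<start>_<stop>_<+/->` coordinate suffix when present
#' (common predictor convention); otherwise the full token is used.
#' Records containing internal stop symbols are split at them, exactly
#' like six-frame output; empty records are skipped with a warning.
#'
#' @param path path to a protein FASTA file (gzip accepted).
#' @return A data.frame with columns `read_id`, `frame` (always
#'   `"predicted"`), `fragment` and `sequence`, as for
#'   [sixFrameTranslate()].
#' @export
readPredictedFragments <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (any(Biostrings::width(aa) == 0L)) {
    warning(sprintf("%d empty record(s) skipped",
                    sum(Biostrings::width(aa) == 0L)))
    aa <- aa[Biostrings::width(aa) != 0L]
  }
  token <- sub("\\s.*$", "", names(aa))
  ids <- sub("_\\d+_\\d+_[+-]$", "", token)
  frags <- .stopSplit(as.character(aa))
  nf <- lengths(frags)
  res <- data.frame(
    read_id = rep(ids, nf),
    frame = rep("predicted", sum(nf)),
    fragment = integer(sum(nf)),
    sequence = unlist(frags, use.names = FALSE),
    stringsAsFactors = FALSE)
  # number fragments consecutively within each read
  res$fragment <- stats::ave(seq_len(nrow(res)), res$read_id,
                             FUN = seq_along)
  res
}

#' Read DNA reads from FASTQ or FASTA
#'
#' Thin convenience wrapper: format is chosen by extension (`.fq`,
#' `.fastq`, optionally `.gz` vs everything else as FASTA); qualities are
#' not retained (the profiler does not use them).
#'
#' @param path input path.
#' @return A named character vector of DNA sequences (names are the first
#'   whitespace-delimited token of each record id).
#' @export
readReads <- function(path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- if (fastq) Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
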