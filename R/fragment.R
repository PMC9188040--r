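#' Fragmentation parameters
#'
#' Describes how protein fragments are broken into peptides: either
#' overlapping fixed-length k-mers (`mode = "kmer"`; the only parameter is
#' `k`, default 9) or non-overlapping variable-length peptides split at a
#' regular expression (`mode = "tryptic"`; the default pattern cleaves
#' after each K or R not followed by P, the in silico trypsin digest, with
#' survivors filtered to `minLen`..`maxLen` residues — defaults 5 and 50,
#' the bounds used when digesting a reference proteome).
#'
#' @param mode `"kmer"` or `"tryptic"`.
#' @param k peptide length for k-mer mode.
#' @param pattern Perl-compatible regex marking cleavage sites for tryptic
#'   mode; the split falls immediately after each match.
#' @param minLen,maxLen tryptic peptide length bounds (inclusive).
#' @return A list of class-free fragmentation parameters, used in
#'   [PipelineConfig-class] and [buildIndex()].
#' @export
fragmentationParams <- function(mode = c("kmer", "tryptic"), k = 9L,
                                pattern = "[KR](?!P)",
                                minLen = 5L, maxLen = 50L) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  if (mode == "tryptic")
    tryCatch(regexpr(pattern, "AK", perl = TRUE),
             error = function(e) stop(sprintf("invalid split pattern: %s",
                                              pattern)))
  list(mode = mode, k = as.integer(k), pattern = pattern,
       minLen = as.integer(minLen), maxLen = as.integer(maxLen))
}

#' Split a protein into non-overlapping peptides at a cleavage pattern
#'
#' Splits after every match of `pattern` (default: after each lysine or
#' arginine residue not followed by proline, emulating a trypsin digest).
#' The output peptides concatenate back to the input.
#'
#' @param protein an amino-acid string.
#' @param pattern Perl-compatible regex; the split point is the end of
#'   each match.
#' @return Character vector of peptides, in order.
#' @export
#' @examples
#' splitTryptic("AAKBBRCCK")   # "AAK" "BBR" "CCK"
#' splitTryptic("AAKPBB")      # "AAKPBB" (K before P: no cleavage)
splitTryptic <- function(protein, pattern = "[KR](?!P)") {
  n <- nchar(protein)
  if (n == 0L) return(character(0))
  m <- gregexpr(pattern, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(protein)
  cut <- m + attr(m, "match.length") - 1L  # last residue of each match
  cut <- cut[cut < n]
  substring(protein, c(1L, cut + 1L), c(cut, n))
}

#' Filter peptides by length
#'
#' Order-preserving subsequence of peptides with length in
#' `[minLen, maxLen]`.
#'
#' @param peptides character vector.
#' @param minLen,maxLen inclusive bounds.
#' @return Character vector of surviving peptides.
#' @export
filterPeptideLength <- function(peptides, minLen, maxLen) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  n <- nchar(peptides)
  peptides[n >= minLen & n <= maxLen]
}

#' All overlapping k-mers of a protein
#'
#' @param protein an amino-acid string.
#' @param k peptide length (>= 1).
#' @return Character vector of the `max(0, nchar - k + 1)` k-mers in
#'   order; the i-th element starts at position i.
#' @export
#' @examples
#' kmerize("ABCDEFGHIJ", 9)  # "ABCDEFGHI" "BCDEFGHIJ"
kmerize <- function(protein, k) {
  if (k < 1L) stop("k must be >= 1")
  n <- nchar(protein)
  if (n < k) return(character(0))
  substring(protein, 1:(n - k + 1L), k:n)
}

# fragment one protein under params; tryptic output is NOT length-filtered
# here (build vs query bounds may differ) -- callers apply bounds.
.fragment <- function(protein, params) {
  if (params$mode == "kmer") kmerize(protein, params$k)
  else splitTryptic(protein, params$pattern)
}
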