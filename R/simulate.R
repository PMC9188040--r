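#' Evaluate an expression with a local, restorable RNG seed
#'
#' All synthetic-data operations are reproducible from a seed without
#' touching the caller's RNG state.
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% 2147483647)
  expr
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic benchmark community
#'
#' Defines the conditions under which the synthetic taxonomy, proteomes
#' and reads are generated. Defaults describe a small two-genus,
#' four-species bacterial community: 20 proteins of 300 residues per
#' species, 500 single-end reads of 100 nt with a 1% per-base
#' substitution rate, and 20% shuffled reads as a negative control.
#' Paired-end simulation uses an insert of mean 500 nt (sd 25).
#'
#' @param nGenera,speciesPerGenus,proteinsPerSpecies,proteinLen community
#'   and proteome size (proteinLen in residues).
#' @param nReads,readLen read simulation size (readLen in nt).
#' @param substitutionRate i.i.d. per-base substitution probability.
#' @param shuffledFraction fraction of reads replaced by per-base
#'   shuffles of themselves (destroying coding signal).
#' @param paired simulate read pairs?
#' @param insertMean,insertSd insert size distribution (nt), paired only.
#' @param table NCBI translation table used for back-translation.
#' @param seed integer master seed; every operation derives from it.
#' @return A validated list of simulation parameters.
#' @export
simulationSpec <- function(nGenera = 2L, speciesPerGenus = 2L,
                           proteinsPerSpecies = 20L, proteinLen = 300L,
                           nReads = 500L, readLen = 100L,
                           substitutionRate = 0.01,
                           shuffledFraction = 0.2,
                           paired = FALSE,
                           insertMean = 500, insertSd = 25,
                           table = "11", seed = 1L) {
  spec <- list(nGenera = as.integer(nGenera),
               speciesPerGenus = as.integer(speciesPerGenus),
               proteinsPerSpecies = as.integer(proteinsPerSpecies),
               proteinLen = as.integer(proteinLen),
               nReads = as.integer(nReads), readLen = as.integer(readLen),
               substitutionRate = substitutionRate,
               shuffledFraction = shuffledFraction,
               paired = isTRUE(paired),
               insertMean = insertMean, insertSd = insertSd,
               table = as.character(table), seed = as.integer(seed))
  with(spec, {
    stopifnot(nGenera >= 1L, speciesPerGenus >= 1L,
              proteinsPerSpecies >= 1L, proteinLen >= 1L,
              nReads >= 1L, readLen >= 3L,
              substitutionRate >= 0, substitutionRate <= 1,
              shuffledFraction >= 0, shuffledFraction <= 1)
  })
  spec
}

#' Synthetic taxonomy: root, one domain, genera, species
#'
#' Node ids are stable functions of the spec (root 1, domain 2, genus i
#' is 100+i, species j of genus i is 1000+100*i+j), so the tree is
#' deterministic.
#'
#' @param spec from [simulationSpec()].
#' @return A [Taxonomy-class] with
#'   `2 + nGenera * (1 + speciesPerGenus)` nodes.
#' @export
makeTaxonomy <- function(spec) {
  g <- seq_len(spec$nGenera)
  s <- seq_len(spec$speciesPerGenus)
  genusId <- 100L + g
  spId <- unlist(lapply(g, function(i) 1000L + 100L * i + s))
  taxonomy(
    ids = c(1L, 2L, genusId, spId),
    names = c("root", "Bacteria", sprintf("Genus%02d", g),
              unlist(lapply(g, function(i)
                sprintf("Genus%02d species%02d", i, s)))),
    ranks = c("no rank", "superkingdom",
              rep("genus", length(genusId)), rep("species", length(spId))),
    parents = c(1L, 1L, rep(2L, length(genusId)),
                unlist(lapply(genusId, rep, spec$speciesPerGenus))))
}

.randomProtein <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                    collapse = "")

# uniformly random synonymous back-translation of a protein
.backTranslate <- function(protein, revCode) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cs <- revCode[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Synthetic reference proteomes with genus-conserved domains
#'
#' Generates `proteinsPerSpecies` random proteins per species. A fixed
#' fraction (0.3) of each species' proteins carry a genus-shared
#' N-terminal half — identical across all species of the genus — so that
#' some peptides resolve only to genus level, spreading index entries
#' over ranks as real reference databases do. Each protein is
#' back-translated into coding DNA with uniformly random synonymous
#' codons, preserving the protein while diversifying the DNA; the DNA is
#' the template for read simulation.
#'
#' @param tax taxonomy from [makeTaxonomy()].
#' @param spec from [simulationSpec()].
#' @return A list with `proteins` (data.frame `id`, `taxon_id`,
#'   `sequence`) and `cds` (named character vector of coding DNA, one
#'   entry per protein).
#' @export
makeProteomes <- function(tax, spec) {
  .withSeed(spec$seed + 1L, {
    gc <- .geneticCode(spec$table)
    revCode <- split(names(gc), gc)[.AA20]
    spPos <- which(tax@ranks == "species")
    spIds <- tax@ids[spPos]
    genusOf <- tax@parents[spPos]
    P <- spec$proteinsPerSpecies
    L <- spec$proteinLen
    nCore <- round(0.3 * P)
    coreLen <- ceiling(L / 2)
    cores <- lapply(unique(genusOf), function(g)
      vapply(seq_len(nCore), function(i) .randomProtein(coreLen),
             character(1)))
    names(cores) <- as.character(unique(genusOf))
    rows <- list()
    for (i in seq_along(spIds)) {
      seqs <- vapply(seq_len(P), function(p) {
        if (p <= nCore)
          paste0(cores[[as.character(genusOf[i])]][p],
                 .randomProtein(L - coreLen))
        else .randomProtein(L)
      }, character(1))
      rows[[i]] <- data.frame(
        id = sprintf("T%d_P%02d", spIds[i], seq_len(P)),
        taxon_id = spIds[i], sequence = seqs, stringsAsFactors = FALSE)
    }
    proteins <- do.call(rbind, rows)
    cds <- vapply(proteins$sequence, .backTranslate, character(1),
                  revCode = revCode, USE.NAMES = FALSE)
    names(cds) <- proteins$id
    list(proteins = proteins, cds = cds)
  })
}

.BASES <- c("A", "C", "G", "T")

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Simulate shotgun reads from synthetic coding DNA
#'
#' Draws reads uniformly from the coding templates (both strands),
#' applies i.i.d. per-base substitutions, and replaces a fraction of the
#' reads by per-base shuffles of themselves — negative controls whose
#' base composition is intact but whose coding signal is destroyed.
#' Paired mode draws an insert and reports the pair under the first
#' mate's id (second mate reverse-complemented from the far end).
#'
#' @param proteomes from [makeProteomes()].
#' @param spec from [simulationSpec()].
#' @return A list with `reads` (named character vector), `mates` (named
#'   character vector or `NULL`), `truth` (named integer vector, read id
#'   -> source species taxon id, non-shuffled reads only) and `shuffled`
#'   (character vector of shuffled read ids).
#' @export
simulateReads <- function(proteomes, spec) {
  .withSeed(spec$seed + 2L, {
    templates <- proteomes$cds
    taxOf <- proteomes$proteins$taxon_id[match(names(templates),
                                               proteomes$proteins$id)]
    tlen <- nchar(templates)
    if (any(tlen < spec$readLen))
      stop("read length exceeds template length")
    n <- spec$nReads
    ids <- sprintf("read%05d", seq_len(n))
    nShuf <- round(spec$shuffledFraction * n)
    shufIdx <- if (nShuf > 0L) sort(sample.int(n, nShuf)) else integer(0)
    substitute1 <- function(s) {
      if (spec$substitutionRate == 0) return(s)
      b <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(b)) < spec$substitutionRate)
      for (p in hit) b[p] <- sample(setdiff(.BASES, b[p]), 1L)
      paste(b, collapse = "")
    }
    shuffle1 <- function(s)
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    reads <- character(n); mates <- if (spec$paired) character(n)
    src <- integer(n)
    for (i in seq_len(n)) {
      t <- sample.int(length(templates), 1L)
      src[i] <- taxOf[t]
      strand <- sample(c("+", "-"), 1L)
      tmpl <- if (strand == "+") templates[[t]] else .revcomp(templates[[t]])
      if (spec$paired) {
        ins <- round(stats::rnorm(1L, spec$insertMean, spec$insertSd))
        ins <- max(spec$readLen, min(tlen[t], ins))
        st <- sample.int(tlen[t] - ins + 1L, 1L)
        frag <- substr(tmpl, st, st + ins - 1L)
        reads[i] <- substitute1(substr(frag, 1L, spec$readLen))
        mates[i] <- substitute1(.revcomp(substr(frag, ins - spec$readLen + 1L,
                                                ins)))
      } else {
        st <- sample.int(tlen[t] - spec$readLen + 1L, 1L)
        reads[i] <- substitute1(substr(tmpl, st, st + spec$readLen - 1L))
      }
    }
    for (i in shufIdx) {
      reads[i] <- shuffle1(reads[i])
      if (spec$paired) mates[i] <- shuffle1(mates[i])
    }
    names(reads) <- ids
    if (spec$paired) names(mates) <- ids
    keep <- setdiff(seq_len(n), shufIdx)
    truth <- stats::setNames(src[keep], ids[keep])
    list(reads = reads, mates = if (spec$paired) mates,
         truth = truth, shuffled = ids[shufIdx])
  })
}

#' Write simulated reads as FASTQ
#'
#' Constant base quality (the profiler does not use qualities).
#'
#' @param reads named character vector of DNA reads.
#' @param path output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write / read the simulation truth table
#'
#' TSV with columns `read_id`, `taxon_id` (`-` for shuffled reads) and
#' `shuffled` (`true`/`false`), no header.
#'
#' @param sim list from [simulateReads()].
#' @param path output path.
#' @return `path`, invisibly (`writeTruthTable`); a list with `truth`
#'   and `shuffled` (`readTruthTable`).
#' @export
writeTruthTable <- function(sim, path) {
  ids <- names(sim$reads)
  shuf <- ids %in% sim$shuffled
  tx <- ifelse(shuf, "-", as.character(sim$truth[ids]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(ids, tx, ifelse(shuf, "true", "false"), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  m <- do.call(rbind, strsplit(readLines(path), "\t", fixed = TRUE))
  shuf <- m[, 3L] == "true"
  list(truth = stats::setNames(as.integer(m[!shuf, 2L]), m[!shuf, 1L]),
       shuffled = m[shuf, 1L])
}
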