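# Independent brute-force oracles. They work from an explicit
# ancestor-or-self matrix obtained by transitive closure of the parent
# adjacency (matrix powers), not from the package's lineage walk.

# random rooted tree with ids 1..n (parent of node i drawn from 1..i-1)
randomTree <- function(n, seed) {
  set.seed(seed)
  parents <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                          integer(1)))
  taxonomy(ids = seq_len(n), names = paste0("t", seq_len(n)),
           ranks = rep("no rank", n), parents = parents)
}

# anc[i, j] is TRUE iff node in row i is an ancestor-or-self of column j
# (positions, not ids; fixture ids must be mapped through match())
ancestorMatrix <- function(tax) {
  n <- length(tax@ids)
  A <- matrix(FALSE, n, n)  # parent -> child adjacency
  pos <- match(tax@parents, tax@ids)
  for (i in seq_len(n)) if (tax@ids[i] != 1L) A[pos[i], i] <- TRUE
  anc <- diag(n) > 0
  repeat {
    nxt <- anc | ((anc %*% A) > 0)
    if (identical(nxt, anc)) break
    anc <- nxt
  }
  anc
}

# deepest node, restricted to the input taxa's lineages, that is an
# ancestor or descendant of every input taxon
oracleLcaStar <- function(tax, anc, members) {
  mpos <- match(members, tax@ids)
  cand <- which(rowSums(anc[, mpos, drop = FALSE]) > 0)
  ok <- vapply(cand, function(c)
    all(anc[c, mpos] | anc[mpos, c]), logical(1))
  cand <- cand[ok]
  depth <- colSums(anc)[cand]
  hit <- cand[depth == max(depth)]
  stopifnot(length(hit) == 1L)  # LCA* is unique
  tax@ids[hit]
}

# input member maximizing the count-weighted number of input taxa on its
# root-to-member path; ties to the smallest id
oracleMrtl <- function(tax, anc, members, w) {
  mpos <- match(members, tax@ids)
  score <- vapply(seq_along(mpos), function(j)
    sum(w[anc[mpos, mpos[j]]]), numeric(1))
  min(members[score == max(score)])
}

# greedy root-to-leaf descent on explicit children lists: descend into
# the heaviest child iff its share of the identifications strictly below
# the current node is >= f
oracleHybrid <- function(tax, anc, members, w, f) {
  mpos <- match(members, tax@ids)
  pos <- match(tax@parents, tax@ids)
  cur <- match(1L, tax@ids)
  repeat {
    kids <- which(pos == cur & tax@ids != 1L)
    mass <- vapply(kids, function(ch) sum(w[anc[ch, mpos]]), numeric(1))
    kids <- kids[mass > 0]; mass <- mass[mass > 0]
    if (!length(kids)) break
    o <- order(-mass, tax@ids[kids])
    if (mass[o[1L]] / sum(mass) >= f) cur <- kids[o[1L]] else break
  }
  tax@ids[cur]
}

# all multisets of size k from n items, as a k x M matrix of item indices
# (combinations with repetition via the standard staircase bijection)
multisets <- function(n, k) {
  cmb <- utils::combn(n + k - 1L, k)
  cmb - (seq_len(k) - 1L)
}

# seed-and-extend oracle: a position is retained iff it lies inside some
# interval (within one segment) that starts and ends on identified items,
# whose internal unidentified runs are all <= g, and which contains a run
# of >= s equal identifications
oracleSeedExtend <- function(track, s, g) {
  keep <- logical(nrow(track))
  for (seg in unique(track$segment)) {
    idx <- which(track$segment == seg)
    t <- track$taxon[idx]
    n <- length(t)
    for (i in seq_len(n)) for (j in i:n) {
      if (is.na(t[i]) || is.na(t[j])) next
      span <- t[i:j]
      runs <- rle(ifelse(is.na(span), -1L, span))
      if (any(runs$values == -1L & runs$lengths > g)) next
      if (!any(runs$values != -1L & runs$lengths >= s)) next
      keep[idx[i:j]] <- TRUE
    }
  }
  keep
}

# enumerate every track of a given length over {taxon a, taxon b, NA}
allTracks <- function(len, a = 10L, b = 11L) {
  grid <- do.call(expand.grid, rep(list(c(a, b, NA)), len))
  lapply(seq_len(nrow(grid)), function(i)
    data.frame(peptide = paste0("p", seq_len(len)),
               taxon = as.integer(unlist(grid[i, ])),
               segment = 1L, stringsAsFactors = FALSE))
}
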