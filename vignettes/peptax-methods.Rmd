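---
title: "Protein-space taxonomic read profiling: model, parameters and design"
author: "peptax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-space taxonomic read profiling: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`peptax` assigns a taxon to each shotgun-metagenomics read (pair) by a
protein-space detour. The premise is that protein sequences diverge more
slowly than the genes encoding them, so exact matching of short peptides
against a reference proteome generalizes to strains absent from the
reference where DNA-level matching fails. The per-read pipeline is a fixed
stage order:

    translate -> fragment -> (tryptic) length filter -> index lookup
              -> seed-and-extend -> low-frequency filter -> aggregate

Each stage is an independent, testable function; `profileReads()` composes
them under a `PipelineConfig`.

### Translation

Six-frame translation guarantees that every coding region of an error-free
read appears intact in one frame, at the price of at least 5/6 of the
translated material being noise that downstream exact matching must
absorb. Conventions, fixed deterministically because they matter for
reproducibility:

* frames +1/+2/+3 start at bases 1/2/3; frame −k is frame +k of the
  reverse complement (so the fragment multiset is invariant under
  reverse-complementing the read);
* stop codons translate to `*` and act as hard fragment separators —
  peptides never span a stop; trailing partial codons are dropped;
* codons containing an ambiguous base translate to `X`, which can never
  match an index entry and therefore self-filters;
* the genetic-code table is user-specified (default 11,
  bacterial/archaeal, matching the communities the method targets) and is
  never inferred from data.

Alternatively, `readPredictedFragments()` adopts protein fragments from an
external short-read gene predictor (FragGeneScan-style FASTA). The
predictor itself is out of scope here: it is a separately published tool
that plugs in, not part of this method. Its hidden Markov model is *not*
re-implemented; the adapter only recovers read ids from headers (stripping
`_start_stop_strand` suffixes when present) and stop-splits the records.

### Fragmentation

Two strategies, with one shared contract (the pattern/k used at query time
must equal the one used at index build time; `profileReads()` refuses
mismatches):

* **k-mers** — all overlapping windows of length *k* (default 9). A
  substitution perturbs at most *k* windows but leaves flanking windows
  matchable, so coverage degrades locally, not per-peptide.
* **tryptic peptides** — non-overlapping, cleaving after each K or R not
  followed by P (the in silico trypsin digest); user-supplied
  Perl-compatible patterns are honored, with the split falling after each
  match. Build-time length bounds default to 5–50 residues; query-time
  bounds belong to the pipeline configuration (the precision presets use
  5–45 and 9–45). Short tryptic peptides carry little taxonomic signal and
  cause spurious matches, which is why the sensitivity-oriented tryptic
  preset raises the minimum length to 9.

### The peptide index

`buildIndex()` maps every peptide of the reference proteome to the LCA* of
the **distinct** taxa of all proteins containing it (set semantics: a
peptide occurring ten times within one species counts that species once).
LCA* — the most specific taxon that is an ancestor or descendant of every
annotating taxon, equivalently the LCA after discarding members that are
strict ancestors of other members — is also the per-read aggregation
default, so a peptide found in a species and (as an annotation artifact)
its genus still resolves to the species.

The serialized form is a lexicographically sorted (byte order),
LF-terminated TSV with a commented metadata header (fragmentation mode and
parameters, plus a checksum of the taxonomy; querying against a different
taxonomy warns). Builds are byte-deterministic and independent of protein
input order. Both an in-memory map and an on-disk binary-search lookup
(`lookupPeptidesDisk()`) are provided; they are behaviorally identical and
tested against each other. The recommended k-mer length is 8–9: shorter
k-mers lose precision to chance matches, longer ones inflate the index and
lose robustness to variation; the command-line index builder warns outside
that range.

### Filtering

* **Seed-and-extend** (`seedExtendFilter()`): within one translated
  fragment — adjacency is never fabricated across fragment, frame or mate
  boundaries — a *seed* is a run of at least *s* consecutive peptides with
  the same consensus taxon. Seeds extend in both directions across
  neighboring identified items (of *any* taxon: the extension step absorbs
  differently-identified singletons, and only unidentified runs count
  toward the gap limit) and across unidentified runs of length at most
  *g*, repeatedly. Everything outside every extended seed is dropped.
  Equivalent formulation, used by the test oracle: a position is retained
  iff it lies in some interval that starts and ends on identified items,
  contains a seed, and has no internal unidentified run longer than *g*.
  Retention is antitone in *s* and monotone in *g*.
* **Low-frequency filter** (`lowFrequencyFilter()`): drops taxa observed
  fewer than *h* times in the read's surviving identification multiset;
  *h* = 1 is the identity. It is applied *after* seed-and-extend — the
  relative order of the two post-lookup filters is a genuinely open
  choice, and counting hits after seed-and-extend makes the frequency
  threshold act on already-locally-consistent evidence.

### Aggregation

All four consensus heuristics act on the count-weighted multiset of
surviving identifications (a frequency table, so occurrences — not
distinct taxa — carry the mass):

* **LCA** — deepest common ancestor of all members;
* **LCA\*** — LCA after discarding strict ancestors of other members;
* **MRTL** — the member whose lineage carries the largest count-weighted
  number of members; always a member of the input;
* **hybrid<sub>f</sub>** — greedy root-to-leaf descent; at each node,
  descend into the heaviest child iff its share of the identification mass
  *strictly below the current node* is at least *f*.

Two conventions deserve emphasis. First, ties (MRTL score ties, equal-mass
children) break deterministically toward the smallest taxon id, making
outputs reproducible and oracle-testable. Second, the hybrid descent
measures mass over *strict* descendants of the current node: a member
sitting at the node itself stops counting once the descent reaches it.
This is the only reading under which hybrid with *f* = 1 coincides exactly
with LCA* (consider the multiset {genus, species-below-it}: LCA* discards
the genus and returns the species; with self-inclusive mass the descent
would stall at the genus). The equivalence, the nesting
LCA ≼ LCA* ≼ hybrid<sub>f</sub> along lineages, and the monotonicity of
hybrid in *f* are all verified exhaustively against brute-force oracles in
the test suite.

Reads whose multiset ends up empty are reported as taxon 1 (the root),
meaning "no identification". Paired-end mates are concatenated into one
track with a break between them before filtering, since both mates come
from one organism.

### Rank snapping, reporting and evaluation

`snapToRank()` maps a prediction to its unique ancestor at a requested
canonical rank; predictions *less* specific than the rank snap to the root
and count as no assignment. Snapping is idempotent. Evaluation follows the
standard confusion matrix over snapped predictions: TP = non-shuffled
reads assigned the expected taxon; FP = non-shuffled reads assigned a
different taxon, plus shuffled reads assigned anything; TN = shuffled
reads left unassigned; FN = non-shuffled reads left unassigned. Reads
whose *expected* taxon is less specific than the evaluation rank are
ignored. Metrics with a zero denominator are reported as 0 and flagged in
`undefined` rather than raising — tiny fixtures routinely produce empty
classes (e.g. no negatives at all). Frequency tables report counts per
(optionally rank-snapped) taxon in a fixed CSV dialect;
`exportTaxonTree()` produces a self-contained hierarchical JSON document
(self and subtree counts per node, conserved up to the root) in place of
any hosted visualization service.

## The synthetic-data generator

The generator defines the package's study conditions; it is first-class,
tested code, not a throwaway fixture.

* `makeTaxonomy()` — root / one domain / genera / species, with stable
  arithmetic ids.
* `makeProteomes()` — uniformly random proteins per species, except that
  30% of each species' proteins carry a genus-shared N-terminal half.
  This conserved-domain fraction (a fixed design constant, not a spec
  knob) makes some peptides resolve only to the genus, reproducing the
  spread of index entries across ranks that real reference databases
  show; without it, every peptide would be species-unique and aggregation
  would never be exercised above the species level. Proteins are
  back-translated into coding DNA with uniformly random synonymous codons
  — the DNA diverges while the protein is preserved, which is precisely
  the regime the protein-space detour assumes.
* `simulateReads()` — reads drawn uniformly from the coding templates
  (both strands), i.i.d. per-base substitutions, and a fraction of reads
  replaced by per-base shuffles of themselves: negative controls with
  intact base composition but destroyed coding signal, which a sound
  pipeline must leave unassigned.

Default conditions: 2 genera × 2 species × 20 proteins × 300 residues;
500 single-end reads of 100 nt; substitution rate 0.01; shuffled fraction
0.20; paired mode with insert 500 ± 25 nt available. All randomness flows
from a single integer seed through a local RNG scope (`.Random.seed` is
saved and restored), so fixtures are bit-reproducible and never perturb
the caller's RNG.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: platform-specific error profiles (indels,
quality-dependent miscalls), realistic phylogenetic divergence (species
differ by construction, not by an evolutionary model), reference databases
with misannotations, horizontal transfer, uneven strain coverage, or
UniProt-scale index sizes. The end-to-end tests demonstrate internal
consistency of the method under controlled conditions (noiseless precision
1.0 at species rank, shuffled reads unassigned, sensitivity degrading with
substitution rate), not field accuracy on real communities.

## Numerical choices and degenerate inputs

* Lexicographic order everywhere means *byte* order (`sort(method =
  "radix")`), independent of the session locale.
* Consensus of an empty multiset is an error at the aggregation API and
  the root taxon at the pipeline level (the pipeline is the place that
  knows "no evidence" is an answer).
* Reads shorter than 3 nt translate to nothing (warning); proteins
  shorter than *k* produce no k-mers; empty tracks pass through filters
  unchanged.
* Taxa flagged invalid in the taxonomy table are kept in the tree but
  identifications landing on them redirect to the nearest valid ancestor
  at index build time, keeping every index value aggregatable.
* The taxonomy checksum in index metadata is a small polynomial hash of
  the serialized node table; a mismatch warns (the index may still be
  semantically fine across cosmetic taxonomy edits) rather than fails.

## Problem sizes in the test suite

The exhaustive suites run at deliberately small scale, chosen so the whole
suite completes in minutes on one core while still covering the full
combinatorial space where that is feasible: consensus heuristics are
checked against brute-force oracles on *all* multisets of size ≤ 4 over a
random 20-node tree (plus 1000 random weighted multisets for the
hybrid/LCA* identity), seed-and-extend against an exhaustive interval
enumerator on *all* tracks of length ≤ 8 over two taxa and a gap symbol
for s ∈ {2,3}, g ∈ {0,1,2}, and the end-to-end recovery on a 250-read
noiseless community. These sizes are the package's own choices of
sufficient evidence, not statements about where the method stops working.

## Known limitations

* Exact matching means zero tolerance per peptide: a single substitution
  voids that peptide (though neighboring k-mers recover the signal);
  frameshifts within a fragment are not corrected.
* The gene-prediction path depends entirely on the external predictor's
  quality; missed coding regions cost sensitivity.
* The hybrid heuristic's arbitrary-tie convention (smallest id) is a
  reproducibility device, not a biological claim.
* Tryptic mode does not expand missed cleavages and does not equalize
  isoleucine/leucine; unusual residues (U, O, B, Z) pass through and
  simply never match.
* The index is rebuilt, not incrementally updated, when the reference or
  taxonomy changes.
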