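---
title: "Assembly-free variant discovery with dbgvar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free variant discovery with dbgvar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgvar)
```

dbgvar analyses raw short-read sequencing data without a reference
genome and without assembling it. Everything rests on one kernel: the
set of *solid canonical k-mers* of the input read sets, queried either
exactly or through a bloom filter, and the implicit de Bruijn graph
(dBG) this set defines. Polymorphisms between samples — or between the
two haplotypes of one sample — leave recognizable local motifs in this
graph, and each caller in the package is a search for one motif class.

This vignette explains the models, the tunable parameters, the
numerical and design choices that were genuinely open, and what the
bundled simulator does and does not establish about real data.

## The kernel: solid canonical k-mers and the implicit graph

A k-mer is a DNA word of length `k` (default 31, the largest value
that packs two bits per base into one machine word). Because reads
come from both strands, membership is always canonical: a k-mer and
its reverse complement are one object, represented by the
lexicographically smaller of the two. Odd `k` is recommended — even
`k` admits words equal to their own reverse complement, which fold the
graph locally (see *Numerical choices*).

Counting scans every k-window of every read, skipping windows that
contain a non-`ACGT` character, and saturates counts at 2^16 − 1
(solidity thresholds are small, so saturation never matters). The
*solid set* keeps the canonical k-mers seen at least `c` times
(default 3). `c` trades error robustness against sensitivity: at 1%
per-base error and 31-mers, roughly a quarter of read windows carry an
error, but each erroneous k-mer is individually rare, so a threshold
of 3–4 removes nearly all of them at 30–40× coverage while genuine
windows keep dozens of supporting reads.

The de Bruijn graph is never materialised. Its nodes are the solid
canonical k-mers; a successor of an oriented k-mer is its (k−1)-suffix
plus one base whose canonical form is solid — at most four membership
queries. Traversal therefore works on *oriented* words while truth
lives in canonical space, which realises the bidirected graph without
doubling storage.

A bloom filter over the solid set is provided as a memory-frugal
prefilter: a plain bit vector of `bits_per_elem × n` bits (default
16), each element setting `h = 7` addresses obtained by double hashing
of the packed k-mer. It never returns false negatives and its
false-positive rate tracks the classical `(1 − e^{−hn/m})^h` closely
(the acceptance script measures the ratio; it is near 1). All
algorithmic decisions in this package are made against the exact set —
the filter exists for footprint experiments and for read-set
comparison at scale, where an occasional false positive only perturbs
a percentage.

## Isolated-SNP bubbles

An isolated substitution between two haplotypes creates two parallel
paths of `k` vertices each, spelling two sequences of length `2k − 1`
that differ at exactly the center position. Detection seeds on two
oriented solid k-mers identical except at their last base and extends
both simultaneously for `k − 1` steps, a step being admissible when
the appended base keeps both paths solid, the two new nodes are
distinct, and neither has appeared on either path before. The
disjointness guard is part of the bubble definition (two
*vertex-disjoint* simple paths): without it, tiny or dense graphs
admit strand-crossing pseudo-paths and pairs of the form
`(x, reverse_complement(x))`, which are one molecule seen from both
strands, not variants.

In `strict` mode (the default) each step must admit *exactly one*
base, so any branching along the way discards the candidate; `relaxed`
mode enumerates all admissible extensions. Strict is the conservative
choice for error-containing data; relaxed is the complete enumeration
of the model and is what the exhaustive test oracle checks against.
Every bubble is reported once, in a canonical form closed under path
swap and reverse complement.

Flanking contigs are shared by both alleles (the paths agree outside
the center). The left contig is the unambiguous unitig extension of
the unique solid predecessor of the shared (k−1)-prefix — if that
predecessor is missing or ambiguous the contig is empty — and the
right contig mirrors this. Unitig walks use the standard
both-sides-unique rule, so a neighboring variant's fork truncates the
flank rather than producing a chimeric contig. Flank length is capped
at 10,000 bases by default: flanks are context, not assemblies.

## Read map-back, allele counts and the phi score

Predicted bubbles are validated by mapping every read of every set
back onto the two flanked allele sequences: a placement must be
ungapped, induced by at least one exact shared k-mer, cover the SNP
position, and carry at most `max_mismatch` mismatches (default 1). A
read whose best placements tie between the two alleles is ambiguous
and counted for neither — dropping, not splitting, keeps the counts
integral and the rule transparent. The mismatch budget and the
ambiguity policy are this package's choices; the tools this design
descends from do not document theirs.

The resulting 2×S table (alleles × read sets) is summarised by the phi
score: with `N` the table total and `chi2` the Pearson statistic over
cells with positive expectation (zero-mass columns skipped),
`phi = sqrt(chi2 / N)`, clamped to `[0, 1]`. This is Cramér's V for a
2-row table, and for two read sets it reduces to the absolute
classical phi coefficient `|ad − bc| / sqrt((a+b)(c+d)(a+c)(b+d))`.
The score is 0 for degenerate tables (no reads, one allele absent
everywhere), 1 for perfect discrimination, invariant under column
permutation, row swap and integer scaling. SNPs are ranked by
descending phi with ties broken by bubble id, so output order is
deterministic.

## Inversion breakpoints

An inverted segment I between flanks a and b (aIb in one genome, aI′b
in the other, ′ denoting reverse complement) leaves four breakpoint
words of length 2k in the joint k-mer content: au, vb, av′ and u′b,
where u and v are the first and last k-mers of I. The motif is two
k-forks closing a pseudo-cycle over the four k-mers a, u, v, b. The
search roots at every solid k-mer with at least two successors,
enumerates its length-k solid extensions (a fork whose partial-path
count exceeds `max_paths`, default 100, is abandoned — this bounds the
blowup repeats would otherwise cause), pairs the extensions into
(u, v′) candidates, and completes each pair with every k-mer b for
which vb and u′b are fully solid.

Two subtleties surfaced during development and are worth knowing:

* **Degenerate closures.** The four-word condition alone is satisfied
  by tuples such as `(a, u, v, a′)`, because `v·a′` is the reverse
  complement of `a·v′` and hence automatically solid. The four k-mers
  of the pseudo-cycle are therefore required to be pairwise
  canonically distinct — except the (u, v) pair, which is equal by
  definition in a palindromic event.
* **The full symmetry orbit.** The word set is invariant not only
  under reverse complement and under exchanging u↔v′, but also under
  swapping the halves `(a,u,v,b) → (v,b,a,u)`: from k-mer content
  alone these denote the same event. The canonical representative
  minimises the serialization over all eight forms; with the smaller
  four-form orbit every event would be reported twice.

Repeats and palindromes mimic the motif — this is the dominant
false-positive mode. The repeat guard (active whenever
`min_fork_distance > 0`) requires `Hamming(u, v′) ≥ min_fork_distance`
(default 3) and first-base divergence at both junction pairs
(`u[1] ≠ v′[1]`, `b[1] ≠ a′[1]`). The second condition catches folds
through chance palindromes and breakpoint micro-homology, where the
breakpoint position is genuinely ambiguous; the Hamming test alone
cannot see these. Setting `min_fork_distance = 0` disables the guard
entirely, which is the only way to observe palindromic events (u =
v′), flagged as such in the output. This guard is a local
dissimilarity test of this package's own design; the tool family it
follows uses a local-complexity filter specified elsewhere, so the two
will not agree on pathological inputs.

Only the breakpoint tuple is reported. The inverted segment itself is
not reconstructed: the motif does not determine it uniquely.

## Targeted assembly around starters

A *starter* is a user sequence anchoring a local exploration. It is
accepted when at least `min_fraction` (default 0.7) of its k-windows
are solid — a starter with one substitution against the sequenced
genome loses `min(k, windows)` windows, which the default tolerates
for typical starter lengths; a foreign starter scores near 0 and is
skipped (starters are not error-corrected). Two outputs are produced:
the *linear extension*, a unitig-rule walk from both ends that stops
as soon as two choices occur; and the *neighborhood graph*, a
breadth-first exploration of compacted unitig nodes up to `max_depth`
branch levels (default 5) or `max_nodes` nodes (default 200), with
deterministic ids from sorted exploration order. Bubbles in this graph
are the polymorphisms adjacent to the starter. Each node carries, per
read set, the mean count of its windows in that set's count table —
a deliberately cheap coverage proxy that matches how such graphs are
colored for inspection; it is not a read-mapping quantification. The
graph serialises to a stable-keyed JSON document (schema shipped under
`inst/extdata/`).

## Read-set comparison

A read of set A is *similar to* set B when it contains at least `t`
k-windows (overlapping allowed, default `t = 2`) present in B's
all-k-mer index (solidity 1). The rule, and especially `t`, is an
interpretation — the similarity criterion of the tool this follows is
defined in an external specification — so it is exposed and recorded
in every output. Per-read flags pack into bit vectors (one bit per
read, file order), which support AND/OR/NOT/ANDNOT algebra and persist
in a small versioned binary format; with a bloom index in place of the
exact one, bits can only be added, never removed. Directed percentages
`pct(A→B) = 100·|similar reads|/|A|` symmetrise as
`100·(shared(A→B)+shared(B→A))/(|A|+|B|)`, and the sets are clustered
by average linkage on `100 − similarity`, with newick output. Leaf
order and tie-breaks follow input order, keeping dendrograms
reproducible.

## The simulator: what the tests do and do not show

The generator produces i.i.d. random genomes (GC fraction 0.5 by
default), plants isolated SNPs and inversions, and simulates
uniform-coverage substitution-error reads (fair strand coin, constant
qualities, no indels — the callers model substitution-induced motifs,
and indel-bearing reads would probe machinery this package
deliberately does not implement). Default study conditions in the
acceptance script: a 100 kb genome with 40 SNPs read at 30× per
haplotype (error-free) and 40× (1% errors, solidity 4), and a 50 kb
genome with 10 inversions of 100–500 bp read at 30× per arrangement —
sizes chosen so the full battery runs in well under a minute on one
core while every graph phenomenon of interest (forks, flank
truncation, error k-mers) still occurs.

Planting enforces constructive guarantees, and this is the crucial
caveat: SNP windows are resampled until all their k-mers are unique
across both genomes; inversion sites are resampled until both k-forks
genuinely branch (`u[1] ≠ v′[1]`, `v[k] ≠ u′[k]`), the terminals clear
the repeat guard (`Hamming(u, v′) ≥ 3`), and there is no breakpoint
micro-homology (the base left of the segment must not complement the
base right of it — otherwise a second, shifted copy of the motif
exists in the data and "the" breakpoint is ill-defined). Under these
conditions perfect recall and precision are theorems, not luck, and
that is exactly what the acceptance checks verify. Real genomes
violate every one of these assumptions: repeats create spurious forks
and abandonments, micro-homology produces families of shifted
breakpoint calls, low-complexity regions defeat the Hamming guard, and
uneven coverage breaks the solidity calculus. Passing tests show the
machinery is a correct implementation of its model — not that the
model's assumptions hold in any particular organism.

Every stochastic step takes an explicit seed, and independent streams
are derived per purpose, so all pipelines are byte-deterministic for a
fixed configuration (asserted by the test suite).

## Numerical choices and degenerate inputs

* k is limited to 31 (2-bit packing in a 64-bit word); k below 3 is
  rejected; even k warns because self-reverse-complement k-mers make
  canonical traversal fold (the test fixtures for unitig properties
  explicitly draw fold-free genomes, validated by a string-level
  oracle, for this reason).
* Counts saturate at 2^16 − 1; solidity thresholds below 1 are
  rejected; an empty solid set yields an all-zero bloom filter that
  answers no to everything.
* Bloom hashing is double hashing over two splitmix64 values of the
  packed canonical k-mer — fixed constants, no runtime seeding, so
  filters are reproducible across sessions.
* Unitig walks guard against loops with a visited set and stop at
  `max_len` (default 10,000 bases).
* Ties everywhere (ranking, clustering, exploration order) break by
  the deterministic input/id order; sorted outputs make runs
  byte-comparable.
* Degenerate phi tables score 0 rather than NA, keeping downstream
  ranking total.

## Known limitations

Close (non-isolated) SNPs and indels fail the bubble model by design;
inversion segments are not reconstructed and events are not
genotyped; paired-end structure is ignored (read sets are unordered
pools); the repeat guard is a stand-in for a published local-complexity
filter; coverage in neighborhood graphs is a k-mer-count proxy, not a
mapping; and the package targets desk-scale data — counting is
in-memory with no disk partitioning, so billion-read datasets are out
of scope.
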