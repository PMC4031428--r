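---
title: "Methods: supertree data curation, MRP coding and Safe Taxonomic Reduction"
author: "supertreeprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supertree data curation, MRP coding and Safe Taxonomic Reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supertreeprep)
```

## The problem

A supertree analysis combines many published source phylogenies into one
large phylogeny, usually by Matrix Representation with Parsimony (MRP).
The analysis itself (PAUP\*, TNT) is the easy part; the work is in the
data: trees must be collected together with the metadata needed to judge
them (publication, characters, analysis type, fossil content), their
taxonomies reconciled, redundant and uninformative trees removed, and
sufficient taxonomic overlap verified. This vignette documents how this
package does each step, which choices were open, and what the tests do
and do not establish.

## The dataset model and its file format

A dataset is a named project holding an ordered list of sources; each
source is one publication (a BibTeX-compatible bibliographic record)
with one or more source trees; each source tree stores the Newick string
plus character data (typed `molecular` / `morphological` /
`behavioural` / `other`), the analysis used, fossil status and optional
figure/page/legend references. Every processing operation appends one
entry (timestamp, operation, parameters) to a history log, so a file
carries its own audit trail.

The on-disk form is a single XML file. The element vocabulary
(`phylo_dataset` / `sources` / `source` / `bibliographic` /
`source_tree` / `history`, versioned by a `format_version` attribute) is
this package's own documented schema. Two properties are load-bearing
and tested:

* **Lossless round trips.** `parsePhyml(writePhyml(ds))` equals `ds`
  field by field, for every generated fixture. Unknown child elements of
  `<source>` and `<source_tree>` (conservation status, accession
  numbers, ...) are preserved as verbatim XML and re-emitted, so
  third-party extensions survive.
* **Deterministic writing.** Fixed element order, attribute order and
  indentation: two writes of the same dataset are byte-identical, which
  makes outputs diffable and golden-file testable.

Trees are stored as Newick text and parsed with `ape`. Branch lengths
and internal node labels are accepted on input and silently discarded:
MRP uses topology only, and discarding them is what makes bit-exact
round trips possible. Taxon names are canonicalised on ingest
(whitespace trimmed, internal spaces to underscores) because the
substitution and genus machinery needs one spelling per taxon; the
convention is `Genus_species`, with genus-level taxa bare single tokens.

## Tree surgery

All surgery maintains two invariants: no internal node has a single
child, and no leaf label occurs twice in a tree.

* **Deletion** removes leaves by base name and collapses the degree-two
  nodes this creates. A tree pruned below two leaves becomes an explicit
  empty-tree sentinel rather than an error: such trees legitimately
  arise mid-pipeline and are removed by `cleanData()`. This
  sentinel-not-error choice keeps long pipelines restartable.
* **Substitution** replaces a leaf by one leaf, by a polytomy of several
  replacements (inserted at the same position), or deletes it. An
  unmarked old name matches every `%d`-marked instance of that taxon.
  When a replacement name already occurs elsewhere in the tree, the
  duplicate is pruned; the tie-break (keep the first occurrence in
  pre-order, prune later ones) is arbitrary but deterministic, which
  matters more here than any particular choice.
* **Polyphyly permutation.** Digitised species-level trees sometimes
  place one taxon in several positions, marked `Bos%1`, `Bos%2`.
  `permuteTree()` enumerates every way of keeping exactly one instance
  per marked taxon (the product over taxa of their instance counts),
  strips the markers, and by default de-duplicates topologically
  identical results — duplicates add nothing to a downstream consensus.
  The consensus itself is deliberately out of scope: permutations are
  written to a treefile for external consensus software. Enumeration
  refuses above $10^6$ permutations unless forced, since the count is
  multiplicative and easy to underestimate.
* **Genus expansion.** As a final step for species-level supertrees,
  `replaceGenera()` replaces each genus-level leaf with a polytomy of
  the congeneric species found anywhere in the dataset (never
  duplicating species already in that tree). Genus detection is "no
  underscore in the name" — a direct consequence of the naming
  convention, not a heuristic. A genus with no congeners in the dataset
  is left in place with a warning, because silently dropping taxa is the
  worse failure mode.

## Informativeness and cleaning

A tree contributes to MRP only through its clades. `isInformative()`
requires at least four leaves and at least one internal node other than
the root subtending two or more, but not all, leaves; `cleanData()`
removes failing trees and then sources left empty. `buildMatrix()`
itself enforces the weaker condition actually required for coding (at
least one informative clade, i.e. a non-star tree on three or more
leaves), so a deliberately kept three-leaf tree still codes; the
cleaning threshold is stricter because trees below four leaves carry no
grouping information once an outgroup roots the analysis.

## MRP coding

`buildMatrix()` implements plain Baum–Ragan coding: one unweighted,
unordered binary character per informative clade of each tree — members
1, the tree's other taxa 0, taxa absent from the tree `?`. The root
clade is excluded (an all-1 column says nothing). Taxa are sorted
lexically; characters follow source order, then tree order, then
pre-order clade order — again for deterministic, diffable output. A
synthetic all-zero `MRP_Outgroup` row (on by default, name fixed) is
prepended for rooting, following standard MRP practice. Matrix validity
is enforced structurally: every column must contain at least one 0 and
one 1 among its known entries.

The key correctness property, tested exhaustively, is self-recovery:
for **every** rooted binary tree on up to six taxa, the MRP matrix of
that single tree, analysed by exhaustive parsimony over all topologies
(with the outgroup), yields the input tree as the unique
most-parsimonious topology. The exhaustive search in the tests is an
independent oracle (phangorn's Fitch parsimony over `allTrees`), never
the package's own code path.

Writers cover NEXUS `DATA` blocks (`SYMBOLS="01" MISSING=?`, names
single-quoted when they need it) and TNT `xread` (which has no quoting
mechanism, so unrepresentable names are rejected with advice to rename
them first). Both writers have matching readers and golden-file tests.

## Safe Taxonomic Reduction

Two taxa are *taxonomically equivalent* when no character is known and
different in both rows. On `{0,1,?}` data the pairwise relations are:

* `identical` — equal rows, including the missing-data pattern;
* `a_subsumed_by_b` — every known entry of *a* is known and equal in
  *b* (and *b* knows more);
* `symmetric_equivalent` — no conflict, but each row has knowns the
  other lacks (complementary missing data — **not** safe to remove);
* `non_equivalent` — some character conflicts.

A subsumed (or identical) taxon contributes no grouping information
beyond its superior's, so removing it cannot change the optimal trees.
The safety argument is short: attaching the removed taxon *a* as sister
to its representative *b* adds zero parsimony steps on every character
(where *a* is known it equals *b*; elsewhere it is free), and removing a
row never increases a tree's score; hence the optima of the reduced and
full matrices coincide, and any reduced optimum with *a* reattached at
*b* attains the full optimum. This is exactly what the safety oracle
tests verify by exhaustive parsimony on random matrices.

Three consequences shaped the implementation:

* **Representatives must be maximal.** Within a chain
  $a \subseteq b \subseteq c$, only *c* can be retained; retaining the
  lexically smallest member would discard information. The removal plan
  therefore retains the maximal rows under subsumption, uses the lexical
  order only to break ties among mutually identical rows, and assigns
  each removed taxon the lexically smallest retained taxon that subsumes
  it (transitivity guarantees one exists).
* **Column dropping is a safety net only.** Because every known entry
  of a removed row is mirrored in its representative, no column of a
  valid matrix can lose a state through removal; the check that drops
  columns left without both a 0 and a 1 exists for robustness on
  hand-edited inputs. This is also why `applyStr()` is idempotent.
* **The `{0,1,?}` restriction buys speed.** The whole pairwise scan
  reduces to two cross-products of indicator matrices: with $K$ the
  known-indicator and $V$ the known-one indicator (characters × taxa),
  conflicts are counted by $V^\top(K-V)$ and its transpose, and
  subsumption by comparing $K^\top K$ with the per-taxon known counts.
  Everything else is elementwise. A 2000-taxon × 5000-character matrix
  classifies and reduces in a few seconds on one CPU; agreement with a
  direct per-pair comparator is oracle-tested at every scale used.

Reports label taxa with category letters. The convention — `A`
identical rows with no missing entries, `B` symmetric equivalence (not
safe), `C` removed because subsumed, `C*` removed because identical to
its representative (exactly reinsertable), `E` no equivalence — is
stated in the report header itself, since the letters are a documented
convention of this package's report format. By default `applyStr()`
removes and reinserts all safely removable taxa;
`restrictIdentical = TRUE` restricts both to identical-row (`C*`)
groups for users who want reinsertion to be exact rather than merely
safe. The reinsertion output is an ordinary substitution file
(`representative = representative, removed1, removed2`), so the same
`substituteTaxa()` machinery that curates names also restores taxa to
the finished supertree as a polytomy at the representative.

## Independence, overlap and subsets

* **Independence.** Non-independent data are defined as trees using
  identical character sets whose taxa are equal or nested. "Identical
  characters" means equality of the sets of character *names*
  (case-insensitive, whitespace-normalised): names are what the format
  stores, so they are the only available notion of character identity.
  Equal taxon sets form an identical group (keep the earliest source by
  year, then citation key); a strict subset flags the smaller tree.
  Removal is suggestion-only unless `autoRemove = TRUE`.
* **Overlap.** The overlap graph has one node per source tree
  (`citationKey:treeIndex`) and an edge when two trees share at least
  *k* taxa. The minimum *k* is 2 and is enforced: one shared taxon
  cannot express any shared grouping. Connectivity uses igraph;
  brute-force reachability serves as the test oracle. Graphs export as
  DOT and GraphML — text formats any graph tool renders, chosen because
  rendered images are out of scope.
* **Subsets.** `createSubset()` filters trees by year range, character
  type, character names, analysis and fossil status, conjunctively;
  filters compose (filtering twice equals filtering by the
  conjunction), which the tests check.

## The synthetic-data generator

`generateDataset()` emulates the *structural* features the pipeline
cares about: random binary topologies over a shared taxon pool with a
tunable probability (`overlapBias`) of re-drawing taxa already used
(at bias 1 each tree is forced to share two taxa with its predecessor,
guaranteeing a connected overlap graph at $k=2$); per-leaf rates for
polyphyletic `%d` splits and genus-level truncation (defaults 0.05 —
occasional, as in digitised real datasets); sampled years, character
vocabularies and analyses; and 4–12 leaves per tree from a pool of 40
across 8 sources, sizes typical of focused published phylogenies
feeding a supertree. All randomness is locally seeded and restores the
caller's RNG state; history timestamps are fixed at the epoch so equal
seeds give byte-identical files. It does **not** emulate evolutionary
realism: no birth–death process, no character evolution, no correlation
between tree shape and metadata. Passing tests therefore establish the
pipeline's algebra (round trips, invariants, recovery, safety), not its
behaviour on any particular empirical distribution of tree shapes.

`generateStrMatrix()` plants known structure on a background that is
conflict-free *by construction*: distinct fully known 0/1 rows always
conflict pairwise, so the only equivalences in the matrix are the
planted identical groups and masked (subsumed) rows, and the ground
truth removal set is exact. A planted masked row can incidentally be
subsumed by a second base row; this changes nothing about which taxa
are removable, which is what recovery tests compare.

## Numerical and degenerate-input choices

* Tie-breaks are lexical in the C locale (radix order) everywhere a
  choice is arbitrary — representatives, removal-plan order, report
  order — so outputs are platform-independent.
* Trees with fewer than two leaves are a sentinel, not an error;
  dataset-level operations keep one-leaf trees as `(X);` for
  `cleanData()` to remove and drop zero-leaf trees with a warning.
* `parseNewick()` accepts missing semicolons and quoted labels, rejects
  unbalanced parentheses and empty labels, and collapses single-child
  nodes on entry, so downstream code can assume the invariants.
* Matrices read from NEXUS/TNT lose provenance (source/tree/clade per
  column become `NA`); everything else works unchanged.

## Problem sizes used by the test suite

Exhaustive MRP self-recovery enumerates all 1068 rooted binary trees on
3–6 taxa against all topologies on up to 7 tips; the STR safety oracle
uses 200 random matrices of up to 7 taxa × 8 characters (the largest
sizes where exhaustive parsimony enumeration stays trivial); round-trip,
permutation, planted-recovery and overlap properties use 100–1000
seeded instances; and the scale check reduces one 2000 × 5000 matrix.
These sizes were chosen so the full suite exercises every claim in
minutes on a single CPU while the exhaustive oracles remain genuinely
exhaustive.

## Known limitations

* STR is restricted to binary `{0,1,?}` matrices — the restriction is
  what the optimisation exploits; multistate data are out of scope.
* Only Baum–Ragan coding is implemented (no Purvis or weighted MRP
  variants), and only NEXUS/TNT matrix output.
* Independence checking sees character *names* only; two studies using
  the same gene under different names will not be flagged.
* Synonym resolution is manual (substitution files); no taxonomy
  database integration.
* The consensus step after polyphyly permutation is left to external
  software.
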