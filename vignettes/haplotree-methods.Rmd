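---
title: "Building and revising binary-marker haplogroup trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and revising binary-marker haplogroup trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotree)
```

## The model

The male-specific region of the Y chromosome does not recombine, so the
genealogy of a sample of Y chromosomes is a single rooted tree.  A binary
marker (SNP) with a known ancestral allele is assumed to have mutated once
on that genealogy; the set of sampled chromosomes carrying its derived
allele — its *carrier set* — is then exactly the clade below the branch on
which the mutation arose.  Under this single-origin assumption a collection
of markers is consistent with one tree **iff** their carrier sets form a
laminar family: any two sets are nested or disjoint.  `haplotree`
implements this logic three ways:

* **de novo**: `build_perfect_phylogeny()` groups markers into
  phylogenetic-equivalence classes (identical carrier sets), checks
  pairwise laminarity, and inserts classes in decreasing carrier-set size,
  each under the deepest class containing it;
* **incrementally**: `update_tree()` integrates newly characterized
  markers into an existing reference tree, classifying every integration
  as `equivalent`, `split_paragroup`, `insert_above`, `join_clades`,
  `reposition` (recurrence-aware) or `unplaced_incompatible`;
* **diagnostically**: `check_compatibility()` reports the witnessed
  violating pairs, and `detect_recurrence()` re-examines markers whose
  fresh carrier data contradict their stored edge.

Haplogroups are named two ways, as in the field's consortium trees: by
mutation (`E-M2`) and "by lineage" (`E1b1a1`), the latter alternating
numbers and letters with depth and assigned positionally from each node's
stored child order.  Chromosomes belonging to a haplogroup but ancestral at
all tested downstream markers form its *paragroup*, written
`E-M35*(xM78,M81,M123,V6)`.

## Missing data and observed witnesses

A haploid call is `ancestral`, `derived`, or `missing`.  A missing call is
unconstrained: the sample leaves the marker's carrier set and never counts
as evidence for or against nesting.  All pairwise relations are therefore
decided by *observed witnesses*: a pair of markers conflicts only when some
sample is derived at both, another derived at the first but observed
ancestral at the second, and a third the reverse.  Two consequences are
deliberate:

* two markers separated only by missing calls are merged onto one edge and
  flagged **order unresolved** rather than ordered arbitrarily;
* with missing data the pairwise criterion is weaker than joint
  realizability (incomplete directed perfect phylogeny is a harder
  problem); the package's compatibility verdict is defined as the pairwise
  test, and the test suite checks its agreement with exhaustive rooted-tree
  enumeration on complete matrices.

## Incremental placement

`assign_samples()` first maps every sample to the deepest node whose
root-path marker classes it carries derived.  A sample derived at
incomparable nodes, or derived at a node but observed ancestral upstream,
is assigned to the deepest *consistent* node and flagged — these conflicts
are precisely the recurrence signals `detect_recurrence()` feeds on, so
they are reported, never silently discarded.

New markers are processed in decreasing carrier-set size (ties broken
lexicographically), so joins are handled before the splits they contain;
assignments are recomputed after every edit, and re-running an update is a
no-op.  A reposition removes the marker's old node and creates its new
one, contributing zero to the created-node count, which keeps the report
invariant `lineages_after - lineages_before = nodes_created` exact.

**Sample-empty subtrees and prior relations.**  A real revision often
cites carrier relations established in earlier surveys for clades the new
panel does not sample.  These enter as an explicit `prior_relations()`
table — *marker X is above marker Y* (Y's clade nests below X) or *X is
disjoint from Y*.  Prior relations are consulted **only** where the panel
is silent: to decide whether a sample-empty child is covered by a new
marker, and to pick between equivalence candidates with identical observed
clades.  Observed genotypes always dominate.  A sample-empty child whose
markers were typed ancestral in the carriers stays a sibling; one that is
fully untyped and undeclared is annotated "order unresolved" instead of
being guessed — in the bundled case study this is exactly how the
unresolved positions of M116.2, P268/P269-type markers, M84 and M290
relative to the new mutations are represented.  Collapsed subtrees are
opaque: attempting to place a marker inside one is an error instructing
the user to expand it first.

## The bundled E1b1 case study

The package ships a complete worked revision of the human Y haplogroup
E1b1 (E-P2): a 44-lineage reference topology (the 2008 consensus, with the
internal structure of E-M191, E-M78 and E-M81 collapsed to counts 6, 11
and 3), the twelve newly characterized markers with their published GRCh37
coordinates, and a 174-chromosome genotype panel expanded from the
published per-panel counts into deterministic pseudo-samples with
population tags.  Running `run_e1b1_update()` reproduces the published
revision: 52 lineages, eight new nodes, E-M2 and E-M329 united under
V38/V100, M154 and M281 repositioned with recurrence flags, M293
interposed above P72, and the rename `E-M2: E1b1a -> E1b1a1`.

Encoding decisions worth recording:

* **Lineage counting.**  The published counts do not state whether the
  subtree root is included; the package counts the root, every explicit
  descendant, plus all collapsed counts, the convention under which the
  reference encoding yields exactly 44 and the revision exactly 52.
* **Prior relations in the fixture.**  The panel contains no E-M329,
  E-M81 or E-P72 carriers, so the V38/V100 join, V257 above M81 and M293
  above P72 rest on previously reported carriers; they are encoded in
  `e1b1_prior_relations()` rather than as invented samples (the panel
  total of 174 is asserted at construction).  P72 is left untyped in the
  panel — it is absent from the survey's exclusion lists — which is what
  routes its ordering to the prior table.
* **Panels without counts** hold one pseudo-sample each so the total is
  174; populations are tagged only where the survey reports them
  (`unspecified` otherwise), and population-conditioned counts only ever
  touch tagged samples.
* **Anchor metadata.**  Coordinates/alleles of pre-existing anchor markers
  are synthetic placeholders (marked as such in `source`); the panel uses
  0/1/`.` state codes, so they are never consulted.
* **Representative names.** A node's mutation-based name uses the first
  of its markers in marker-table order, with an explicit override for the
  V16/M281 clade (reported as E-V16, the name under which it was
  surveyed).

## Serialization

Newick has no native multi-marker edge labels, so the package's dialect
stores each node's class, collapsed count and label in a bracketed comment,
`[&markers=V38|V100,collapsed=6,label=E1b1]`, with `|` separating class
members; a parent/child TSV edge list is the tabular alternative.  Writers
emit children in **stored order** (not sorted): by-lineage names are
positional, and sorting on write would silently rename untouched clades
after a round trip.  Output is still byte-deterministic for a given tree,
and both formats round-trip shape, order, classes, collapsed counts and
labels exactly.

## The synthetic-data generator

`simulate_tree()` grows a topology by uniform attachment until the
requested leaf count, draws a Poisson number of mutations per branch
(zero-mutation internal branches are contracted; leaf branches draw
zero-truncated counts so every requested leaf is realized — retained
branches therefore carry zero-truncated Poisson marker counts), and
optionally lets markers recur on a second, independently chosen branch —
the simplest mechanism consistent with how repositioned markers such as
M154/M281 may in truth be recurrent.  `simulate_genotypes()` attaches
samples to *every* node (internal nodes hold paragroup samples, mirroring
real survey panels), derives each sample along its root path, then applies
i.i.d. missingness.  A single integer seed makes tree, genotypes and file
output byte-reproducible; the generator saves and restores the global RNG
state so it leaves no footprint.

What the generator does *not* emulate: coalescent branch lengths and
demography, genotyping error (wrong calls rather than missing ones),
population structure in missingness, and marker ascertainment bias.
Passing recovery tests therefore demonstrates correctness of the
combinatorial machinery on clean and moderately incomplete data, not
robustness to miscalls.

## Problem sizes and numerical choices

The default test suite exercises: exact topology recovery on 100 seeded
noise-free panels with up to 16 leaves and 2 samples per node; structural
correctness (no misplacement beyond flagged unresolved merges) on 20
panels at 10% missingness with 3 samples per node; agreement of the
compatibility verdict with exhaustive rooted-forest enumeration on all
4,096 complete 4-sample x 3-marker matrices plus 200 random 5 x 4
matrices; 100 serialization round trips; and idempotence/order-invariance
of the updater on stripped-and-replaced simulated trees.  These sizes keep
the whole suite under a minute while covering every placement category.
Ties in processing order are broken lexicographically; equivalence-chain
ambiguities default to the deepest candidate and are flagged; degenerate
inputs (empty carrier sets, all-missing panels, markerless roots) are
reported rather than errored where the survey workflow would continue.

## Known limitations

* Recurrence handling is single-marker: a marker is detached and
  re-placed; joint optimization over several incompatible markers
  (general maximum parsimony) is out of scope.
* The pairwise compatibility criterion can accept jointly unrealizable
  missing-data matrices (see above); for survey-scale marker panels this
  has not been limiting, and violations still surface at placement time.
* Lineage-name parsing assumes fewer than ten siblings per node when
  names are read back visually; the namer itself has no such limit.
* Diploid or phased autosomal data, probabilistic placement under
  genotyping-error models, and placement onto networks are non-goals.
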