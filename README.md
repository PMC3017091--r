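# haplotree

Build and revise Y-chromosome haplogroup phylogenies from haploid
binary-marker genotypes with known ancestral states.

The male-specific region of the Y chromosome does not recombine, so a set
of binary markers (SNPs), each assumed to mutate once, defines a single
rooted tree in which every marker's *carrier set* — the chromosomes bearing
its derived allele — is a clade.  Markers fit one tree exactly when their
carrier sets form a **laminar family** (any two nested or disjoint).
`haplotree` is for population geneticists and forensic analysts who curate
such trees: it builds them de novo by perfect phylogeny, incrementally
places newly characterized markers onto a reference topology (classifying
each event as `equivalent`, `split_paragroup`, `insert_above`,
`join_clades`, `reposition`, or `unplaced_incompatible`), detects
phylogenetic equivalence and recurrent mutation, resolves paragroups
(`E-M35*(xM78,M81,M123,V6)` notation), and regenerates hierarchical
"by lineage" names (`E1b1a1`) alongside mutation-based names (`E-M2`).
A seeded synthetic-data generator with known truth makes every stage
testable, and a bundled case study reproduces the revision of haplogroup
E1b1 (E-P2) — the most common Y haplogroup in Africa — from 44 to 52
lineages.

## Worked example: the E1b1 revision

```r
library(haplotree)
res <- run_e1b1_update()
print(res$report)
#> Haplogroup tree update
#>   lineages: 44 -> 52  (8 new nodes)
#>   events:   equivalent=4, insert_above=3, join_clades=1, reposition=2, split_paragroup=4
#>   renames:
#>     E-M2: E1b1a -> E1b1a1
#>     E-M329: E1b1c -> E1b1a2
#>     ...
#>     E-M154: E1b1a4 -> E1b1a1g1c
#>     E-V16: E1b1b1d -> E1b1b2
```

Reading the numbers: the 44-lineage reference tree gains exactly 8 nodes
(52 = 44 + 8).  One `join_clades` event (V100, with V38 equivalent to it)
unites E-M2 and E-M329 into a new haplogroup E-V38, reducing E1b1 to two
basal branches — hence E-M2's rename from E1b1a to E1b1a1.  Three
`insert_above` events interpose V68 above M78, V257 above M81 and M293
above P72; four `split_paragroup` events carve V39, V23, V42 and V92 out
of existing paragroups; two `reposition` events move M154 (to the E-U209
clade) and M281 (onto one edge with V16) with recurrence flags raised,
since a marker that fits different positions in different panels may have
arisen more than once.  Four `equivalent` events absorb V38, V43, V95 and
V16 into existing edges.  Paragroup labels reflect the revised topology:

```r
paragroup_label(res$tree, "U209", c("U290", "P59", "M154", "V39"))
#> [1] "E-U209*(xU290,P59,M154,V39)"
```

The same machinery is exposed as a command line
(`Rscript inst/cli/haplotree.R <build|update|assign|simulate|recover> ...`)
and as configuration-driven functions (`run_update()`,
`run_simulation()`, `run_recovery()`).

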