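Package: haplotree
Title: Binary-Marker Haplogroup Trees: Construction, Incremental Placement
    and By-Lineage Nomenclature
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and revising Y-chromosome haplogroup
    phylogenies from haploid binary-marker genotypes with known ancestral
    states. Provides a rooted-tree container whose edges carry marker
    equivalence classes, perfect-phylogeny construction with laminar-family
    compatibility checking, incremental placement of newly characterized
    markers onto a reference tree (equivalence, paragroup splitting,
    interposition, clade joining, and recurrence-aware repositioning),
    hierarchical "by lineage" (YCC-style) nomenclature with paragroup
    exclusion labels, annotated Newick and tabular tree serialization, a
    seeded synthetic-data generator with known truth, and a bundled case
    study revising the haplogroup E1b1 phylogeny from 44 to 52 lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
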