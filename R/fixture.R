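## Bundled case study: the revision of the human Y-chromosome haplogroup
## E1b1 (E-P2) phylogeny by twelve newly characterized binary markers.
##
## The reference topology is the 2008 consensus E1b1 subtree (44 lineages
## once the collapsed sub-haplogroups of E-M191, E-M78 and E-M81 -- 6, 11
## and 3 lineages respectively -- are counted).  The genotype panel encodes
## the published survey of 174 chromosomes drawn from thirteen previously
## classified haplogroup/paragroup panels; per-panel counts are expanded
## into deterministic pseudo-samples (panel code + zero-padded index) with
## population tags so that population-conditioned counts are computable.
## Panels listed without an explicit count hold one sample each.

#' Marker table for the E1b1 case study
#'
#' The twelve newly characterized markers (with their published GRCh37
#' coordinates and mutations) are read from the bundled TSV; the fourteen
#' previously known anchor markers genotyped alongside them predate the
#' survey and their coordinates/alleles are synthetic placeholders (marked
#' in `source`), never consulted because the bundled genotypes use 0/1
#' state codes.
#'
#' @return A [marker_table()] of 26 markers, anchors first.
#' @export
e1b1_markers <- function() {
  new <- read_marker_table(system.file("extdata", "e1b1_new_markers.tsv",
                                       package = "haplotree"))
  anchors <- c("M2", "M329", "M215", "M35", "M78", "M81", "M123", "M34",
               "V6", "U209", "U290", "P59", "M154", "M281")
  marker_table(
    name = c(anchors, new$name),
    position = c(1e6 + seq_along(anchors), new$position),
    ancestral = c(rep("A", length(anchors)), new$ancestral),
    derived = c(rep("G", length(anchors)), new$derived),
    rs_id = c(rep(NA_character_, length(anchors)), new$rs_id),
    source = c(rep("prior classification (synthetic placeholder metadata)",
                   length(anchors)), new$source))
}

#' Reference E1b1 tree (pre-revision topology)
#'
#' The 2008 consensus subtree rooted at E1b1 (P2): basal trifurcation into
#' E-M2, E-M215 and E-M329; M154 a direct child of M2 and M281 a child of
#' M35, their pre-revision positions.  E-M191, E-M78 and E-M81 carry
#' collapsed counts of 6, 11 and 3 unshown sub-haplogroups, giving 44
#' lineages under [count_lineages()].
#'
#' @return A `haplo_tree`.
#' @export
e1b1_reference_tree <- function() {
  t <- haplo_tree("E1b1", "P2")
  t <- ht_add_child(t, "E1b1", "M2")
  t <- ht_add_child(t, "E1b1", "M215")
  t <- ht_add_child(t, "E1b1", "M329")
  for (m in c("M58", "M116.2", "M149", "M154", "M155"))
    t <- ht_add_child(t, "M2", m)
  t <- ht_add_child(t, "M2", c("M10", "M66", "M156", "M195"))
  t <- ht_add_child(t, "M2", "M191", collapsed = 6L)
  t <- ht_add_child(t, "M2", "U175")
  t <- ht_add_child(t, "U175", "U209")
  t <- ht_add_child(t, "U209", "U290")
  t <- ht_add_child(t, "U209", "P59")
  t <- ht_add_child(t, "M215", "M35")
  t <- ht_add_child(t, "M35", "M78", collapsed = 11L)
  t <- ht_add_child(t, "M35", "M81", collapsed = 3L)
  t <- ht_add_child(t, "M35", "M123")
  t <- ht_add_child(t, "M123", "M34")
  t <- ht_add_child(t, "M34", "M84")
  t <- ht_add_child(t, "M35", "M281")
  t <- ht_add_child(t, "M35", "V6")
  t <- ht_add_child(t, "M35", "P72")
  ht_validate(t)
  t
}

## panel expansion helper: n pseudo-samples with deterministic ids
.panel <- function(code, n, prior, population = "unspecified") {
  data.frame(id = sprintf("%s_%03d", code, seq_len(n)),
             population = population, prior_haplogroup = prior,
             stringsAsFactors = FALSE)
}

#' Genotype panel for the E1b1 case study
#'
#' 174 pseudo-samples across thirteen panels, typed at 26 markers (the
#' twelve new markers plus fourteen previously known markers including the
#' re-genotyped M154 and M281).  P72 is deliberately untyped (it is absent from the panel's exclusion
#' lists), which is what leaves its order relative to M293 to prior
#' evidence.  Internal consistency (95 = 9 + 86; 45-sample former E-M35*
#' panel with at least 32 text-enumerable resolutions; 174 total) is
#' asserted at construction.
#'
#' @return A [genotype_matrix()].
#' @export
e1b1_genotypes <- function() {
  mt <- e1b1_markers()
  panels <- rbind(
    .panel("EM2x", 3, "E-M2*"),
    .panel("EU209x", 95, "E-U209*(xU290,P59)"),
    .panel("EV39", 1, "E-V39"),
    .panel("EM215x", 5, "E-M215*"),
    .panel("EM35x", 45, "E-M35*(xM78,M81,M123,V6)"),
    .panel("EM78", 1, "E-M78"),
    .panel("EV257x", 1, "E-V257*"),
    .panel("EM34", 18, "E-M34*"),
    .panel("EV23", 1, "E-V23"),
    .panel("EM293x", 1, "E-M293*"),
    .panel("EV42", 1, "E-V42"),
    .panel("EV92", 1, "E-V92"),
    .panel("EV16", 1, "E-V16"))
  stopifnot(nrow(panels) == 174L)
  # population tags where the survey reports them
  pop <- function(ids, value) panels$population[panels$id %in% ids] <<- value
  id <- function(code, i) sprintf("%s_%03d", code, i)
  pop(id("EU209x", 10:95), "sub-Saharan Africa")
  pop(id("EM35x", 1:9), "Europe")
  pop(id("EM35x", 10), "northern Africa")
  pop(id("EM35x", 11:26), "southern Africa")
  pop(id("EM35x", 27:45), "eastern Africa")
  pop(id("EM34", 1:16), "Africa")
  calls <- matrix("ancestral", nrow = nrow(panels), ncol = nrow(mt),
                  dimnames = list(panels$id, mt$name))
  der <- function(ids, markers) calls[ids, markers] <<- "derived"
  m2_path <- c("M2", "V43", "V95", "V38", "V100")
  # E-V38 side
  der(id("EM2x", 1:3), m2_path)
  der(id("EU209x", 1:95), c(m2_path, "U209"))
  der(id("EU209x", 1:9), "M154")
  der(id("EU209x", 10:11), "V39")
  der(id("EV39", 1), c(m2_path, "U209", "V39"))
  # E-M215 side
  der(id("EM215x", 1:5), c("M215", "V16", "M281"))
  der(id("EV16", 1), c("M215", "V16", "M281"))
  der(id("EM35x", 1:45), c("M215", "M35"))
  der(id("EM35x", 1:3), "V68")                     # Europe, E-V68*(xM78)
  der(id("EM35x", c(4:7, 10, 27)), "V257")         # 4 Europe, Berber, Oromo
  der(id("EM35x", c(11:26, 28:31)), "M293")        # 16 southern + 4 eastern
  der(id("EM35x", 32:33), "V42")                   # Ethiopian Jews
  der(id("EM35x", 34), "V92")                      # Amhara
  der(id("EM78", 1), c("M215", "M35", "M78", "V68"))
  der(id("EV257x", 1), c("M215", "M35", "V257"))
  der(id("EM34", 1:18), c("M215", "M35", "M123", "M34"))
  der(id("EM34", 1:2), "V23")
  der(id("EV23", 1), c("M215", "M35", "M123", "M34", "V23"))
  der(id("EM293x", 1), c("M215", "M35", "M293"))
  der(id("EV42", 1), c("M215", "M35", "V42"))
  der(id("EV92", 1), c("M215", "M35", "V92"))
  # fixture consistency: the published panel arithmetic must hold
  u209 <- calls[grepl("^EU209x", rownames(calls)), ]
  stopifnot(sum(u209[, "M154"] == "derived") == 9L,
            sum(u209[, "M154"] == "ancestral") == 86L,
            sum(u209[u209[, "M154"] == "ancestral", "V39"] ==
                  "derived") == 2L)
  m35 <- calls[grepl("^EM35x", rownames(calls)), ]
  resolved <- rowSums(m35[, c("V68", "V257", "M293", "V42", "V92")] ==
                        "derived") > 0
  stopifnot(sum(resolved) >= 32L)
  genotype_matrix(panels, calls, mt)
}

#' Previously reported marker relations for the E1b1 case study
#'
#' The 174-chromosome panel contains no E-M329, E-M81 or E-P72 carriers,
#' so four published placements cannot be recovered from its carrier sets
#' alone: V38 and V100 were found derived in E-M329 chromosomes (and V43 /
#' V95 ancestral there), V257 in all tested E-M81 chromosomes, and M293 in
#' P72-derived chromosomes.  These relations, reported in earlier surveys,
#' are what the placement engine consults for sample-empty subtrees.
#'
#' @return A [prior_relations()] table.
#' @export
e1b1_prior_relations <- function() {
  prior_relations(
    marker   = c("V38", "V100", "V43", "V95", "M293", "V257"),
    relation = c("above", "above", "disjoint", "disjoint", "above", "above"),
    target   = c("M329", "M329", "M329", "M329", "P72", "M81"))
}

#' The full E1b1 case-study bundle
#'
#' @return A list with `tree` (reference topology), `markers`,
#'   `genotypes`, `prior` ([e1b1_prior_relations()]), `new_markers` (the
#'   twelve new markers plus the re-genotyped M154 and M281) and
#'   `priority` (representative-marker override so the V16/M281 clade is
#'   reported as E-V16, the name under which it was surveyed).
#' @export
e1b1_fixture <- function() {
  new <- read_marker_table(system.file("extdata", "e1b1_new_markers.tsv",
                                       package = "haplotree"))
  list(tree = e1b1_reference_tree(),
       markers = e1b1_markers(),
       genotypes = e1b1_genotypes(),
       prior = e1b1_prior_relations(),
       new_markers = c(new$name, "M154", "M281"),
       priority = "V16")
}
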