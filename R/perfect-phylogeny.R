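## De-novo perfect-phylogeny construction from binary characters with known
## ancestral states.  With haploid single-origin markers, a set of markers
## fits one rooted tree iff their carrier sets form a laminar family: any
## two are nested or disjoint.  Missing calls are unconstrained -- a sample
## missing at a marker is excluded from its carrier set and never counts as
## evidence against nesting, so all pairwise relations are decided on
## jointly observed samples only.

#' Carrier set of a marker
#'
#' @param matrix A [genotype_matrix()].
#' @param marker Marker name present in the matrix.
#' @return A `carrier_set`: list with `marker`, `carriers` (sample ids
#'   observed derived), `ancestral` (sample ids observed ancestral) and
#'   `universe` (all sample ids).  Missing calls appear in neither set.
#' @export
carrier_set <- function(matrix, marker) {
  if (!marker %in% colnames(matrix$calls))
    stop("unknown marker: ", marker)
  col <- matrix$calls[, marker]
  structure(list(marker = marker,
                 carriers = rownames(matrix$calls)[col == "derived"],
                 ancestral = rownames(matrix$calls)[col == "ancestral"],
                 universe = rownames(matrix$calls)),
            class = "carrier_set")
}

carrier_sets <- function(matrix, markers = colnames(matrix$calls)) {
  out <- lapply(markers, function(m) carrier_set(matrix, m))
  names(out) <- markers
  out
}

## Pairwise relation between two carrier sets, on observed data only:
##   "violation"  overlap without nesting, witnessed on both sides
##   "a_above_b"  / "b_above_a"  strict nesting with a witness
##   "equivalent" no distinguishing observation (identical on shared samples)
##   "disjoint"   no common carrier and not equivalent
.cs_relation <- function(a, b) {
  ab <- length(intersect(a$carriers, b$carriers)) > 0L
  a_wit <- length(intersect(a$carriers, b$ancestral)) > 0L  # a-derived, b-anc
  b_wit <- length(intersect(b$carriers, a$ancestral)) > 0L  # b-derived, a-anc
  if (!ab) return("disjoint")
  if (a_wit && b_wit) return("violation")
  if (a_wit) return("a_above_b")   # b nested inside a
  if (b_wit) return("b_above_a")   # a nested inside b
  "equivalent"                     # no distinguishing observation
}

#' Check pairwise compatibility of carrier sets
#'
#' Markers with known ancestral states fit a single rooted tree exactly when
#' their carrier sets are pairwise nested or disjoint (a laminar family).  A
#' violating pair overlaps without nesting, witnessed by observed states:
#' some sample derived at both, some derived at the first and ancestral at
#' the second, and vice versa.
#'
#' @param sets A list of [carrier_set()] objects over one sample universe.
#' @return A list with `compatible` (logical) and `violations` (data.frame
#'   with columns `marker1`, `marker2`).
#' @export
check_compatibility <- function(sets) {
  v1 <- character(); v2 <- character()
  n <- length(sets)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (.cs_relation(sets[[i]], sets[[j]]) == "violation") {
          v1 <- c(v1, sets[[i]]$marker)
          v2 <- c(v2, sets[[j]]$marker)
        }
      }
    }
  }
  list(compatible = length(v1) == 0L,
       violations = data.frame(marker1 = v1, marker2 = v2,
                               stringsAsFactors = FALSE))
}

#' Partition markers into phylogenetic-equivalence classes
#'
#' Two markers are phylogenetically equivalent when their carrier sets are
#' identical after excluding samples missing at either marker.  Because
#' missingness makes this relation non-transitive in principle, classes are
#' the connected components of the pairwise relation; a class is flagged
#' ambiguous when any two members' raw carrier sets differ (i.e. the
#' identity holds only thanks to missing data).
#'
#' @param matrix A [genotype_matrix()].
#' @param markers Markers to consider (default: all columns).
#' @return A list with `classes` (list of character vectors) and
#'   `ambiguous` (logical vector, one per class).
#' @export
find_equivalent <- function(matrix, markers = colnames(matrix$calls)) {
  sets <- carrier_sets(matrix, markers)
  n <- length(sets)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  amb <- rep(FALSE, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (.cs_relation(sets[[i]], sets[[j]]) == "equivalent") {
          if (!setequal(sets[[i]]$carriers, sets[[j]]$carriers))
            amb[c(i, j)] <- TRUE
          comp[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- split(markers, roots)
  flags <- vapply(split(amb, roots), any, logical(1))
  names(classes) <- NULL
  list(classes = unname(classes), ambiguous = unname(flags))
}

#' Build a haplogroup tree de novo by perfect phylogeny
#'
#' Standard construction for binary characters with known ancestral states:
#' markers are grouped into equivalence classes, classes are checked for
#' laminarity, then inserted in order of decreasing carrier-set size, each
#' under the deepest class whose carriers contain it.  A class strictly
#' contained in another with no observed distinguishing sample (an
#' empty-residual nesting, possible under missingness) is merged onto the
#' containing edge and flagged "order unresolved".
#'
#' @param matrix A [genotype_matrix()].
#' @param root_label Label for the root node.
#' @return A `haplo_tree`.  Markers with no derived observations are left
#'   off the tree and recorded in `attr(tree, "unplaced")`.  An incompatible
#'   matrix is an error of class `haplotree_incompatible` whose `violations`
#'   field lists the offending marker pairs.
#' @export
build_perfect_phylogeny <- function(matrix, root_label = "root") {
  eq <- find_equivalent(matrix)
  unplaced <- character()
  cls_sets <- list()
  for (k in seq_along(eq$classes)) {
    members <- eq$classes[[k]]
    sets <- carrier_sets(matrix, members)
    carriers <- unique(unlist(lapply(sets, `[[`, "carriers")))
    ancestral <- setdiff(unique(unlist(lapply(sets, `[[`, "ancestral"))),
                         carriers)
    if (!length(carriers)) { unplaced <- c(unplaced, members); next }
    cls_sets[[length(cls_sets) + 1L]] <-
      list(marker = paste(members, collapse = "|"), members = members,
           carriers = carriers, ancestral = ancestral,
           unresolved = eq$ambiguous[k])
  }
  chk <- check_compatibility(cls_sets)
  if (!chk$compatible) {
    cond <- structure(
      class = c("haplotree_incompatible", "error", "condition"),
      list(message = paste0(
             "markers incompatible with a single tree: ",
             paste(chk$violations$marker1, chk$violations$marker2,
                   sep = " / ", collapse = "; ")),
           call = sys.call(-1), violations = chk$violations))
    stop(cond)
  }
  ord <- order(-lengths(lapply(cls_sets, `[[`, "carriers")),
               vapply(cls_sets, `[[`, character(1), "marker"))
  cls_sets <- cls_sets[ord]
  tree <- haplo_tree(root_label)
  node_sets <- list(list(carriers = rownames(matrix$calls),
                         ancestral = character()))  # root covers everyone
  for (cs in cls_sets) {
    # descend to the deepest placed class containing this one
    host <- 1L
    repeat {
      nxt <- 0L
      for (c in tree$children[[host]]) {
        if (.cs_relation(cs, node_sets[[c]]) == "b_above_a") { nxt <- c; break }
      }
      if (nxt == 0L) break
      host <- nxt
    }
    kids <- tree$children[[host]]
    rels <- vapply(kids, function(c) .cs_relation(cs, node_sets[[c]]),
                   character(1))
    if (any(rels == "equivalent")) {
      # empty-residual nesting: no observed sample separates the two
      # classes, so they share one edge, flagged "order unresolved"
      tgt <- kids[which(rels == "equivalent")[1L]]
      tree$markers[[tgt]] <- c(tree$markers[[tgt]], cs$members)
      tree$unresolved[[tgt]] <- union(tree$unresolved[[tgt]], cs$members)
      node_sets[[tgt]]$carriers <- union(node_sets[[tgt]]$carriers,
                                         cs$carriers)
      node_sets[[tgt]]$ancestral <- setdiff(
        union(node_sets[[tgt]]$ancestral, cs$ancestral),
        node_sets[[tgt]]$carriers)
      next
    }
    contained <- kids[rels == "a_above_b"]
    if (length(contained) == 0L) {
      tree <- ht_add_child(tree, host, cs$members)
    } else if (length(contained) == 1L) {
      tree <- ht_insert_above(tree, contained, cs$members)
    } else {
      tree <- ht_join_children(tree, host, contained, cs$members)
    }
    nid <- ht_n(tree)
    node_sets[[nid]] <- cs
    if (cs$unresolved) tree$unresolved[[nid]] <- cs$members
  }
  attr(tree, "unplaced") <- unplaced
  ht_validate(tree)
  tree
}
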