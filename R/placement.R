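## Incremental integration of markers into an existing reference tree.
##
## Placement is driven by set relations between a marker's carrier set and
## the sample sets of existing clades (laminar-family logic), with two
## refinements mirroring how published trees are actually revised:
##
##  * samples are assigned to their deepest consistent haplogroup first, so
##    paragroup membership (assigned exactly at a node) is well defined;
##  * subtrees with no sampled representatives cannot be ordered by the
##    panel itself; an optional `prior_relations` table of previously
##    reported carrier relations (marker "above" or "disjoint" with an
##    existing marker) resolves them.  Observed genotypes always dominate:
##    prior relations are consulted only where the panel is silent.

#' Declare previously reported marker relations
#'
#' @param marker Character vector of (new) marker names.
#' @param relation `"above"` (the target's clade is known from prior data to
#'   nest below the marker) or `"disjoint"` (known to lie on a different
#'   branch).
#' @param target Character vector of markers already on the reference tree.
#' @return A `prior_relations` data.frame.
#' @export
prior_relations <- function(marker, relation, target) {
  relation <- match.arg(relation, c("above", "disjoint"), several.ok = TRUE)
  out <- data.frame(marker = as.character(marker),
                    relation = rep_len(relation, length(marker)),
                    target = as.character(target),
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_relations", "data.frame")
  out
}

## ---------------------------------------------------------------------------

#' Assign samples to haplogroups
#'
#' Each sample is mapped to the deepest node all of whose root-path marker
#' classes it carries in the derived state (missing calls are
#' unconstrained).  A sample derived at incomparable nodes, or derived at a
#' node while observed ancestral on that node's root path, is assigned to
#' the deepest *consistent* node and flagged as a conflict naming the
#' offending markers -- such signals are what recurrence detection feeds on.
#' The paragroup flag is set when at least one child edge of the assigned
#' node was tested and found ancestral.
#'
#' @param tree A `haplo_tree`.
#' @param matrix A [genotype_matrix()].
#' @param exclude Genotyped markers to ignore (markers not yet placed on the
#'   tree must be listed here explicitly).
#' @return A data.frame with one row per sample: `sample`, `node_id`,
#'   `haplogroup` (mutation-based name), `is_paragroup`, `excluded`
#'   (comma-joined markers tested ancestral on child edges, stored order),
#'   `conflict`, `note`.
#' @export
assign_samples <- function(tree, matrix, exclude = character()) {
  typed <- colnames(matrix$calls)
  on_tree <- vapply(typed, function(m) !is.na(ht_node_of_marker(tree, m)),
                    logical(1))
  stray <- typed[!on_tree & !(typed %in% exclude)]
  if (length(stray))
    stop("genotyped marker(s) neither on the tree nor excluded: ",
         paste(stray, collapse = ", "))
  use <- typed[on_tree & !(typed %in% exclude)]
  node_of <- vapply(use, function(m) ht_node_of_marker(tree, m), integer(1))
  depth <- vapply(seq_len(ht_n(tree)), function(v) ht_depth(tree, v),
                  integer(1))
  n_samp <- nrow(matrix$calls)
  res <- data.frame(sample = rownames(matrix$calls),
                    node_id = NA_integer_, haplogroup = NA_character_,
                    is_paragroup = FALSE, excluded = "",
                    conflict = FALSE, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_samp)) {
    st <- matrix$calls[i, use]
    der_nodes <- unique(node_of[st == "derived"])
    anc_by_node <- split(use[st == "ancestral"], node_of[st == "ancestral"])
    notes <- character()
    # class-internal contradictions (derived at one member, ancestral at
    # another of the same edge)
    mixed <- intersect(as.character(der_nodes), names(anc_by_node))
    for (v in mixed)
      notes <- c(notes, paste0("mixed states within class ",
                               paste(tree$markers[[as.integer(v)]],
                                     collapse = "/")))
    assigned <- ht_root(tree)
    conflict <- length(mixed) > 0L
    if (length(der_nodes)) {
      cand <- der_nodes[order(-depth[der_nodes])]
      pick <- NA_integer_
      for (d in cand) {
        path <- setdiff(ht_path_to_root(tree, d), ht_root(tree))
        anc_on_path <- intersect(as.character(setdiff(path, d)),
                                 names(anc_by_node))
        # a node observed ancestral on the path blocks assignment there
        # unless the same node was also observed derived
        anc_on_path <- setdiff(as.integer(anc_on_path), der_nodes)
        if (!length(anc_on_path)) { pick <- d; break }
        der_here <- use[st == "derived" & node_of == d][1L]
        blockers <- unlist(anc_by_node[as.character(anc_on_path)])
        notes <- c(notes, paste0(
          "derived at ", der_here, " but ancestral at upstream ",
          paste(blockers, collapse = ","), "; recurrence suspected"))
        conflict <- TRUE
      }
      if (is.na(pick)) pick <- ht_root(tree)
      assigned <- pick
      off_path <- setdiff(der_nodes, ht_path_to_root(tree, assigned))
      if (length(off_path)) {
        conflict <- TRUE
        notes <- c(notes, paste0(
          "derived at incomparable clades: ",
          paste(vapply(off_path, function(v)
            paste(tree$markers[[v]], collapse = "/"), character(1)),
            collapse = " vs "),
          " vs assigned"))
      }
    }
    # paragroup: child edges of the assigned node tested ancestral
    excl <- character()
    for (c in tree$children[[assigned]]) {
      mks <- intersect(tree$markers[[c]], use)
      obs <- st[match(mks, use)]
      if (any(obs == "ancestral", na.rm = TRUE) &&
          !any(obs == "derived", na.rm = TRUE))
        excl <- c(excl, mks[obs == "ancestral"])
    }
    res$node_id[i] <- assigned
    res$is_paragroup[i] <- length(excl) > 0L
    res$excluded[i] <- paste(excl, collapse = ",")
    res$conflict[i] <- conflict
    res$note[i] <- paste(unique(notes), collapse = "; ")
  }
  res$haplogroup <- vapply(res$node_id, function(v)
    mutation_name(tree, v, marker_order = matrix$markers$name), character(1))
  res
}

## sample sets per node from an assignment table
.node_sets <- function(tree, assignments) {
  n <- ht_n(tree)
  exact <- split(assignments$sample, factor(assignments$node_id, 1:n))
  clade <- vector("list", n)
  for (v in seq_len(n))
    clade[[v]] <- unlist(exact[as.character(ht_descendants(tree, v))],
                         use.names = FALSE)
  list(exact = exact, clade = clade)
}

.prior_for <- function(prior, marker) {
  if (is.null(prior)) return(list(above = character(), disjoint = character()))
  p <- prior[prior$marker == marker, , drop = FALSE]
  list(above = p$target[p$relation == "above"],
       disjoint = p$target[p$relation == "disjoint"])
}

.placement_event <- function(marker, category, anchors = character(),
                             created = FALSE, recurrence_flag = FALSE,
                             note = "", net_created = as.integer(created)) {
  structure(list(marker = marker, category = category, anchors = anchors,
                 created = created, recurrence_flag = recurrence_flag,
                 note = note, net_created = net_created),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(x$marker, ": ", x$category,
      if (length(x$anchors)) paste0(" [", paste(x$anchors, collapse = ", "),
                                    "]"),
      if (x$recurrence_flag) " (recurrence)",
      if (nzchar(x$note)) paste0(" -- ", x$note), "\n", sep = "")
  invisible(x)
}

#' Place one new marker on a tree
#'
#' Categorizes the marker by the relation of its carrier set to existing
#' clades and applies the corresponding edit: `equivalent` (carriers match
#' an existing clade; the marker joins that edge's class),
#' `split_paragroup` (carriers form a new clade inside a node's paragroup),
#' `insert_above` (carriers are a clade plus part of its parent's
#' paragroup; a node is interposed on the clade's parent edge),
#' `join_clades` (carriers are the union of two or more sibling clades; a
#' node is created above exactly those siblings), or
#' `unplaced_incompatible` (carriers overlap a clade without nesting).
#' Subtrees with no sampled carriers are ordered by `prior` where given and
#' otherwise annotated "order unresolved".  Collapsed subtrees are opaque:
#' no marker may be placed inside one.
#'
#' @param tree A `haplo_tree`.
#' @param marker Marker name (must not already be on the tree; see
#'   [detect_recurrence()] for re-genotyped markers).
#' @param carriers A [carrier_set()] for the marker.
#' @param assignments Output of [assign_samples()] against `tree`.
#' @param prior Optional [prior_relations()].
#' @param matrix Optional [genotype_matrix()]; when supplied, a sample-empty
#'   subtree whose markers were typed ancestral in the carriers is kept as a
#'   sibling, while a fully untyped one is annotated "order unresolved".
#'   Without it every undeclared sample-empty sibling is annotated
#'   unresolved.
#' @return A list with the (possibly modified) `tree` and the
#'   `placement_result` event.
#' @export
place_marker <- function(tree, marker, carriers, assignments, prior = NULL,
                         matrix = NULL) {
  if (!is.na(ht_node_of_marker(tree, marker)))
    stop("marker ", marker,
         " is already on the tree; use detect_recurrence()")
  C <- carriers$carriers
  if (!length(C))
    return(list(tree = tree,
                event = .placement_event(marker, "unplaced_no_carriers",
                                         note = "no derived observations")))
  if (!all(C %in% assignments$sample))
    stop("carriers of ", marker,
         " are not a subset of the tree's sample universe: ",
         paste(setdiff(C, assignments$sample), collapse = ", "))
  ns <- .node_sets(tree, assignments)
  pr <- .prior_for(prior, marker)
  # laminarity of C against every explicit clade
  viol <- integer()
  for (v in seq_len(ht_n(tree))[-1L]) {
    O <- intersect(C, ns$clade[[v]])
    if (length(O) && !setequal(O, C) && !setequal(O, ns$clade[[v]]))
      viol <- c(viol, v)
  }
  if (length(viol)) {
    # keep only minimal (deepest) violating clades
    keep <- viol[!vapply(viol, function(v)
      any(viol != v & vapply(viol, function(w)
        w != v && ht_is_ancestor(tree, v, w), logical(1))), logical(1))]
    anchors <- vapply(keep, function(v)
      paste(tree$markers[[v]], collapse = "/"), character(1))
    return(list(tree = tree, event = .placement_event(
      marker, "unplaced_incompatible", anchors = anchors,
      note = paste0("carriers overlap clade(s) without nesting: ",
                    paste(anchors, collapse = "; ")))))
  }
  above_nodes <- vapply(pr$above, function(m) ht_node_of_marker(tree, m),
                        integer(1))
  above_nodes <- above_nodes[!is.na(above_nodes)]
  disjoint_nodes <- vapply(pr$disjoint, function(m)
    ht_node_of_marker(tree, m), integer(1))
  disjoint_nodes <- disjoint_nodes[!is.na(disjoint_nodes)]
  # host: deepest node containing all carriers and (strictly) all
  # known-below subtrees
  ok_host <- function(v) {
    all(C %in% ns$clade[[v]]) &&
      all(vapply(above_nodes, function(t)
        t != v && ht_is_ancestor(tree, v, t), logical(1)))
  }
  hosts <- which(vapply(seq_len(ht_n(tree)), ok_host, logical(1)))
  depth <- vapply(seq_len(ht_n(tree)), function(v) ht_depth(tree, v),
                  integer(1))
  h <- hosts[which.max(depth[hosts])]
  if (tree$collapsed[h] > 0L)
    stop("placement of ", marker, " falls inside the collapsed subtree of ",
         mutation_name(tree, h),
         "; expand the subtree before updating")
  # equivalence: an existing edge with exactly this sample set, compatible
  # with the declared prior relations
  equiv_ok <- function(v) {
    v != ht_root(tree) && setequal(ns$clade[[v]], C) &&
      all(vapply(above_nodes, function(t)
        t != v && ht_is_ancestor(tree, v, t), logical(1))) &&
      !any(vapply(disjoint_nodes, function(t)
        ht_is_ancestor(tree, v, t) || ht_is_ancestor(tree, t, v),
        logical(1)))
  }
  eq_cand <- which(vapply(seq_len(ht_n(tree)), equiv_ok, logical(1)))
  if (length(eq_cand)) {
    v <- eq_cand[which.max(depth[eq_cand])]
    note <- ""
    if (length(eq_cand) > 1L) {
      tree$unresolved[[v]] <- union(tree$unresolved[[v]], marker)
      note <- "order unresolved within an equivalence chain"
    }
    tree$markers[[v]] <- c(tree$markers[[v]], marker)
    return(list(tree = tree, event = .placement_event(
      marker, "equivalent", anchors = mutation_name(tree, v), note = note)))
  }
  # classify the host's children
  kids <- tree$children[[h]]
  covered <- logical(length(kids))
  unresolved_sibs <- character()
  for (k in seq_along(kids)) {
    c_id <- kids[k]
    cl <- ns$clade[[c_id]]
    if (length(cl)) {
      covered[k] <- all(cl %in% C)
    } else {
      # sample-empty subtree: orderable only by prior relations or by
      # observed ancestral calls in the carriers
      if (any(vapply(above_nodes, function(t)
        ht_is_ancestor(tree, c_id, t), logical(1)))) {
        covered[k] <- TRUE
      } else {
        sub_markers <- unlist(tree$markers[ht_descendants(tree, c_id)])
        typed <- FALSE
        if (!is.null(matrix)) {
          cols <- intersect(sub_markers, colnames(matrix$calls))
          if (length(cols))
            typed <- any(matrix$calls[C, cols, drop = FALSE] != "missing")
        }
        if (!typed)
          unresolved_sibs <- c(unresolved_sibs, tree$markers[[c_id]][1L])
      }
    }
  }
  K <- kids[covered]
  if (length(K) == 0L) {
    tree <- ht_add_child(tree, h, marker)
    nid <- ht_n(tree)
    tree$unresolved[[nid]] <- unresolved_sibs
    note <- if (length(unresolved_sibs))
      paste0("order relative to ", paste(unresolved_sibs, collapse = ","),
             " unresolved (no typed carriers)") else ""
    return(list(tree = tree, event = .placement_event(
      marker, "split_paragroup", anchors = mutation_name(tree, h),
      created = TRUE, note = note)))
  }
  if (length(K) == 1L) {
    anchor <- mutation_name(tree, K)
    tree <- ht_insert_above(tree, K, marker)
    nid <- ht_n(tree)
    tree$unresolved[[nid]] <- unresolved_sibs
    return(list(tree = tree, event = .placement_event(
      marker, "insert_above", anchors = anchor, created = TRUE)))
  }
  anchors <- vapply(K, function(v) mutation_name(tree, v), character(1))
  tree <- ht_join_children(tree, h, K, marker)
  nid <- ht_n(tree)
  tree$unresolved[[nid]] <- unresolved_sibs
  list(tree = tree, event = .placement_event(
    marker, "join_clades", anchors = anchors, created = TRUE))
}

#' Re-examine a marker already on the tree against fresh carrier data
#'
#' A previously mapped marker whose new carrier set contradicts its stored
#' edge is detached and re-placed.  When detaching and re-placing yields a
#' single valid position the event is a `reposition` with the recurrence
#' flag raised (a marker that fits two positions in different data sets may
#' well have arisen more than once); when even the detached marker cannot
#' be placed, the event is `unplaced_incompatible` and the tree is left
#' untouched.  Carriers consistent with the stored edge produce a
#' `consistent` no-op event.
#'
#' @inheritParams place_marker
#' @param matrix The [genotype_matrix()] backing `assignments` (used to
#'   re-assign samples on the detached tree).
#' @param exclude Markers to ignore during internal re-assignment (passed
#'   through to [assign_samples()]).
#' @return A list with `tree` and the `placement_result` event.
#' @export
detect_recurrence <- function(tree, marker, carriers, matrix,
                              prior = NULL, exclude = character()) {
  v <- ht_node_of_marker(tree, marker)
  if (is.na(v)) stop("marker ", marker, " is not on the tree")
  assignments <- assign_samples(tree, matrix, exclude = exclude)
  ns <- .node_sets(tree, assignments)
  C <- carriers$carriers
  clade <- ns$clade[[v]]
  consistent <- all(C %in% clade) &&
    !any(clade %in% carriers$ancestral)
  if (consistent)
    return(list(tree = tree, event = .placement_event(
      marker, "consistent", anchors = mutation_name(tree, v),
      net_created = 0L)))
  old_name <- mutation_name(tree, v)
  det <- ht_detach_marker(tree, marker)
  excl2 <- union(exclude, marker)
  assignments2 <- assign_samples(det$tree, matrix, exclude = excl2)
  placed <- place_marker(det$tree, marker, carriers, assignments2,
                         prior = prior, matrix = matrix)
  if (placed$event$category %in% c("unplaced_incompatible",
                                   "unplaced_no_carriers")) {
    ev <- placed$event
    ev$note <- paste0("stored at ", old_name, "; still unplaceable after ",
                      "detaching: ", ev$note)
    return(list(tree = tree, event = ev))  # original tree, untouched
  }
  ev <- placed$event
  ev$category <- "reposition"
  ev$recurrence_flag <- TRUE
  ev$net_created <- as.integer(placed$event$created) -
    as.integer(det$removed_node)
  ev$note <- paste0("repositioned from ", old_name,
                    "; recurrent origin cannot be excluded",
                    if (nzchar(placed$event$note))
                      paste0("; ", placed$event$note) else "")
  list(tree = placed$tree, event = ev)
}

#' Incrementally update a reference tree with newly characterized markers
#'
#' Markers are processed in deterministic order (decreasing carrier-set
#' size, ties broken lexicographically) so that clade-joining markers are
#' handled before the splits they contain; each placement is applied before
#' the next marker is considered and sample assignments are recomputed
#' after every edit.  Markers already on the tree are routed through
#' [detect_recurrence()]; new markers through [place_marker()].  Running
#' the update a second time with the same markers is a no-op.
#'
#' @param tree The reference `haplo_tree`.
#' @param matrix A [genotype_matrix()] whose typed markers are each either
#'   on the tree or in `new_markers`.
#' @param new_markers Markers to (re)examine.
#' @param prior Optional [prior_relations()] encoding previously reported
#'   carrier relations for subtrees the panel does not sample.
#' @param priority Optional representative-marker override for naming.
#' @param exclude_markers Genotyped markers to ignore entirely (typed in
#'   the matrix but deliberately not examined in this update).
#' @return A list with the updated `tree` and an `update_report`: lineage
#'   counts before/after, the event list, the number of created nodes, the
#'   rename map, and the final sample assignments.
#' @export
update_tree <- function(tree, matrix, new_markers, prior = NULL,
                        priority = NULL, exclude_markers = character()) {
  ht_validate(tree)
  new_markers <- as.character(new_markers)
  absent <- setdiff(new_markers, colnames(matrix$calls))
  if (length(absent))
    stop("new marker(s) not genotyped: ", paste(absent, collapse = ", "))
  sizes <- vapply(new_markers, function(m)
    sum(matrix$calls[, m] == "derived"), integer(1))
  ord <- order(-sizes, new_markers)
  queue <- new_markers[ord]
  before <- count_lineages(tree)
  old_tree <- tree
  events <- list()
  for (m in queue) {
    cs <- carrier_set(matrix, m)
    on_tree <- !is.na(ht_node_of_marker(tree, m))
    # markers from the queue that are (still) off the tree must be masked
    # from assignment, including any that failed to place earlier
    off_queue <- setdiff(queue, unlist(tree$markers))
    step <- if (on_tree) {
      detect_recurrence(tree, m, cs, matrix, prior = prior,
                        exclude = union(off_queue, exclude_markers))
    } else {
      asg <- assign_samples(tree, matrix,
                            exclude = union(off_queue, exclude_markers))
      place_marker(tree, m, cs, asg, prior = prior, matrix = matrix)
    }
    tree <- step$tree
    events[[length(events) + 1L]] <- step$event
    ht_log("placed ", m, ": ", step$event$category,
           if (nzchar(step$event$note)) paste0(" (", step$event$note, ")"))
  }
  after <- count_lineages(tree)
  created <- sum(vapply(events, `[[`, integer(1), "net_created"))
  if (after - before != created)
    stop("internal error: lineage delta ", after - before,
         " != created nodes ", created)
  report <- structure(list(
    lineages_before = before,
    lineages_after = after,
    nodes_created = created,
    events = events,
    renames = rename_report(old_tree, tree, priority = priority,
                            marker_order = matrix$markers$name),
    assignments = assign_samples(tree, matrix,
                                 exclude = setdiff(colnames(matrix$calls),
                                                   unlist(tree$markers)))),
    class = "update_report")
  list(tree = tree, report = report)
}

#' @export
print.update_report <- function(x, ...) {
  cat("Haplogroup tree update\n")
  cat("  lineages: ", x$lineages_before, " -> ", x$lineages_after,
      "  (", x$nodes_created, " new nodes)\n", sep = "")
  tab <- table(vapply(x$events, `[[`, character(1), "category"))
  cat("  events:   ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (nrow(x$renames)) {
    cat("  renames:\n")
    for (i in seq_len(nrow(x$renames)))
      cat("    ", x$renames$mutation_name[i], ": ",
          x$renames$former[i], " -> ", x$renames$current[i], "\n", sep = "")
  }
  invisible(x)
}

ht_log <- function(...) {
  if (isTRUE(getOption("haplotree.verbose"))) message(...)
  invisible(NULL)
}
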