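#' @keywords internal
"_PACKAGE"

## Genotype states used throughout the package. Haploid data only: a call is
## ancestral, derived, or missing; there is no heterozygous state.
.STATES <- c("ancestral", "derived", "missing")

#' Construct a marker table
#'
#' A marker is a binary Y-chromosome polymorphism with a known ancestral and
#' derived allele. The table is an ordinary `data.frame` (class
#' `marker_table`) with one row per marker; row order doubles as the default
#' representative-marker priority used by [mutation_name()].
#'
#' @param name Character vector of unique marker names (e.g. `"V38"`).
#' @param position 1-based coordinates on the GRCh37 Y reference.
#' @param ancestral,derived Single-nucleotide ancestral/derived alleles
#'   (`A`, `C`, `G` or `T`); the two must differ for every marker.
#' @param rs_id Optional dbSNP identifiers (`NA` where none exists).
#' @param source Free-text provenance, e.g. `"present study"` or a citation
#'   key.
#' @return A `marker_table` data.frame with columns `name`, `position`,
#'   `ancestral`, `derived`, `rs_id`, `source`.
#' @export
#' @examples
#' marker_table("V38", 6818291, "C", "T", rs_id = "rs768983",
#'              source = "present study")
marker_table <- function(name, position, ancestral, derived,
                         rs_id = NA_character_, source = NA_character_) {
  name <- as.character(name)
  position <- as.numeric(position)
  ancestral <- toupper(as.character(ancestral))
  derived <- toupper(as.character(derived))
  n <- length(name)
  rs_id <- rep_len(as.character(rs_id), n)
  source <- rep_len(as.character(source), n)
  if (anyDuplicated(name))
    stop("duplicate marker names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(!is.finite(position) | position <= 0))
    stop("marker positions must be positive")
  bad <- !(ancestral %in% c("A", "C", "G", "T")) |
    !(derived %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("alleles must be one of A, C, G, T (markers: ",
         paste(name[bad], collapse = ", "), ")")
  if (any(ancestral == derived))
    stop("ancestral and derived alleles must differ (markers: ",
         paste(name[ancestral == derived], collapse = ", "), ")")
  out <- data.frame(name = name, position = position, ancestral = ancestral,
                    derived = derived, rs_id = rs_id, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Map an observed allele to a genotype state
#'
#' @param marker A one-row slice of a [marker_table()] (or any list with
#'   `name`, `ancestral` and `derived` entries).
#' @param observed_allele A single nucleotide, or `NA`/`NULL`/`"."` for no
#'   data.
#' @return `"derived"`, `"ancestral"` or `"missing"`.  An allele matching
#'   neither listed allele is an error (possible tri-allelic site or strand
#'   problem) rather than a silent missing call.
#' @export
#' @examples
#' v38 <- marker_table("V38", 6818291, "C", "T")
#' genotype_to_state(v38, "T")  # "derived"
#' genotype_to_state(v38, "C")  # "ancestral"
#' genotype_to_state(v38, NA)   # "missing"
genotype_to_state <- function(marker, observed_allele) {
  if (is.null(observed_allele) || length(observed_allele) == 0)
    return("missing")
  a <- toupper(as.character(observed_allele))
  if (is.na(a) || a == "." || a == "")
    return("missing")
  if (a == marker$derived)  return("derived")
  if (a == marker$ancestral) return("ancestral")
  stop("allele '", a, "' at marker ", marker$name,
       " matches neither the ancestral (", marker$ancestral,
       ") nor the derived (", marker$derived,
       ") allele; possible tri-allelic site or strand problem")
}

#' Construct a haploid genotype matrix
#'
#' @param samples A data.frame with columns `id` (unique sample identifiers)
#'   and optionally `population` and `prior_haplogroup`.
#' @param calls A character matrix of states (`"ancestral"`, `"derived"`,
#'   `"missing"`), rows in the order of `samples$id`, columns named by
#'   marker.
#' @param markers The [marker_table()] the columns refer to; every column
#'   must name a marker in it.
#' @return A `genotype_matrix` object (list with `samples`, `calls`,
#'   `markers`).
#' @export
genotype_matrix <- function(samples, calls, markers) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$id)) stop("samples must have an 'id' column")
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (is.null(samples$population)) samples$population <- NA_character_
  if (is.null(samples$prior_haplogroup))
    samples$prior_haplogroup <- NA_character_
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(samples))
    stop("calls must have one row per sample")
  if (is.null(colnames(calls)))
    stop("calls must have marker names as column names")
  unknown <- setdiff(colnames(calls), markers$name)
  if (length(unknown))
    stop("calls reference markers absent from the marker table: ",
         paste(unknown, collapse = ", "))
  bad <- !(calls %in% .STATES)
  if (any(bad))
    stop("calls must be one of ", paste(.STATES, collapse = "/"),
         "; offending values: ",
         paste(utils::head(unique(calls[bad]), 5), collapse = ", "))
  rownames(calls) <- samples$id
  structure(list(samples = samples, calls = calls, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Haploid genotype matrix: ", nrow(x$calls), " samples x ",
      ncol(x$calls), " markers\n", sep = "")
  tab <- table(factor(x$calls, levels = .STATES))
  cat("  calls: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## HaploTree: rooted tree; node 1 is the root; each non-root node carries a
## non-empty marker equivalence class on its subtending edge. `children`
## stores explicit child order (lineage names are positional).

#' Create a haplogroup tree with a single (root) node
#'
#' @param root_label Optional display name for the root haplogroup (e.g.
#'   `"E1b1"`).  The first letter of the label is used as the major-clade
#'   letter in mutation-based names.
#' @param root_markers Markers carried on the root's own subtending edge in
#'   the larger phylogeny (may be empty).
#' @return A `haplo_tree` object.
#' @seealso [ht_add_child()], [count_lineages()], [lineage_names()]
#' @export
haplo_tree <- function(root_label = NA_character_,
                       root_markers = character()) {
  structure(list(parent = NA_integer_,
                 children = list(integer()),
                 markers = list(as.character(root_markers)),
                 collapsed = 0L,
                 label = as.character(root_label),
                 unresolved = list(character())),
            class = "haplo_tree")
}

ht_n <- function(tree) length(tree$parent)
ht_root <- function(tree) 1L

#' Add a child haplogroup to a tree
#'
#' @param tree A `haplo_tree`.
#' @param parent Parent node: a node id, a marker name, or a node label.
#' @param markers Non-empty character vector, the marker equivalence class
#'   on the new edge.
#' @param collapsed Number of descendant haplogroups not shown explicitly
#'   (a node with `collapsed > 0` stands for that many unexpanded lineages).
#' @param label Optional display label.
#' @param at Optional 1-based position in the parent's child order
#'   (default: appended last).
#' @return The extended tree.
#' @export
ht_add_child <- function(tree, parent, markers, collapsed = 0L,
                         label = NA_character_, at = NULL) {
  pid <- ht_find(tree, parent)
  markers <- as.character(markers)
  if (!length(markers)) stop("a non-root node needs at least one marker")
  clash <- markers[markers %in% unlist(tree$markers)]
  if (length(clash))
    stop("marker(s) already on the tree: ", paste(clash, collapse = ", "))
  nid <- ht_n(tree) + 1L
  tree$parent[nid] <- pid
  tree$children[[nid]] <- integer()
  tree$markers[[nid]] <- markers
  tree$collapsed[nid] <- as.integer(collapsed)
  tree$label[nid] <- as.character(label)
  tree$unresolved[[nid]] <- character()
  kids <- tree$children[[pid]]
  if (is.null(at) || at > length(kids)) kids <- c(kids, nid)
  else kids <- append(kids, nid, after = at - 1L)
  tree$children[[pid]] <- kids
  tree
}

## Resolve a node reference (id, marker name, or label) to a node id.
ht_find <- function(tree, what) {
  if (is.numeric(what)) {
    id <- as.integer(what)
    if (id < 1L || id > ht_n(tree)) stop("no node with id ", id)
    return(id)
  }
  what <- as.character(what)
  hit <- which(vapply(tree$markers, function(m) what %in% m, logical(1)))
  if (length(hit) == 1L) return(hit)
  hit <- which(!is.na(tree$label) & tree$label == what)
  if (length(hit) == 1L) return(hit[1L])
  stop("no node matches '", what, "'")
}

ht_node_of_marker <- function(tree, marker) {
  hit <- which(vapply(tree$markers, function(m) marker %in% m, logical(1)))
  if (length(hit)) hit[1L] else NA_integer_
}

ht_descendants <- function(tree, id, include_self = TRUE) {
  out <- integer()
  stack <- id
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(stack, tree$children[[v]])
  }
  if (!include_self) out <- setdiff(out, id)
  out
}

ht_path_to_root <- function(tree, id) {
  out <- integer()
  while (!is.na(id)) {
    out <- c(out, id)
    id <- tree$parent[id]
  }
  out
}

ht_is_ancestor <- function(tree, a, b) {
  # TRUE iff a is an ancestor of b (strict) or a == b
  a %in% ht_path_to_root(tree, b)
}

ht_depth <- function(tree, id) length(ht_path_to_root(tree, id)) - 1L

#' Validate haplogroup-tree invariants
#'
#' Checks that each marker labels at most one edge, that every non-root node
#' carries at least one marker, that collapsed counts are non-negative, and
#' that parent/child bookkeeping is consistent.  Called by readers and the
#' placement engine; returns the tree invisibly or stops.
#'
#' @param tree A `haplo_tree`.
#' @export
ht_validate <- function(tree) {
  n <- ht_n(tree)
  if (sum(is.na(tree$parent)) != 1L || !is.na(tree$parent[1L]))
    stop("tree must have exactly one root at node 1")
  all_markers <- unlist(tree$markers)
  if (anyDuplicated(all_markers))
    stop("marker appears on two edges: ",
         paste(unique(all_markers[duplicated(all_markers)]), collapse = ", "))
  empties <- which(lengths(tree$markers) == 0L)
  if (length(setdiff(empties, 1L)))
    stop("non-root node(s) without defining markers: ",
         paste(setdiff(empties, 1L), collapse = ", "))
  if (any(tree$collapsed < 0L)) stop("collapsed counts must be >= 0")
  for (v in seq_len(n)[-1L]) {
    if (!(v %in% tree$children[[tree$parent[v]]]))
      stop("child bookkeeping inconsistent at node ", v)
  }
  if (length(ht_descendants(tree, 1L)) != n)
    stop("tree contains unreachable nodes")
  invisible(tree)
}

#' Count marker-defined lineages in a subtree
#'
#' Counts the subtree root, every explicit descendant haplogroup, and all
#' lineages hidden inside collapsed sub-haplogroups (the `collapsed` counts).
#' This is the convention under which the bundled E1b1 reference tree holds
#' 44 lineages and its revision 52.
#'
#' @param tree A `haplo_tree`.
#' @param root_label The subtree root: a node label (e.g. `"E1b1"`) or a
#'   marker name; defaults to the tree root.
#' @return A non-negative integer.
#' @export
count_lineages <- function(tree, root_label = NULL) {
  id <- if (is.null(root_label)) ht_root(tree) else ht_find(tree, root_label)
  sub <- ht_descendants(tree, id)
  length(sub) + sum(tree$collapsed[sub])
}

## Insert a new node on the edge above `child`: the new node takes the
## child's slot in its parent's child order and adopts the child.
ht_insert_above <- function(tree, child, markers, label = NA_character_) {
  cid <- ht_find(tree, child)
  if (cid == ht_root(tree)) stop("cannot insert above the root")
  pid <- tree$parent[cid]
  markers <- as.character(markers)
  clash <- markers[markers %in% unlist(tree$markers)]
  if (length(clash))
    stop("marker(s) already on the tree: ", paste(clash, collapse = ", "))
  nid <- ht_n(tree) + 1L
  tree$parent[nid] <- pid
  tree$children[[nid]] <- cid
  tree$markers[[nid]] <- markers
  tree$collapsed[nid] <- 0L
  tree$label[nid] <- as.character(label)
  tree$unresolved[[nid]] <- character()
  kids <- tree$children[[pid]]
  kids[kids == cid] <- nid
  tree$children[[pid]] <- kids
  tree$parent[cid] <- nid
  tree
}

## Group existing siblings under a new node which takes the slot of the
## first grouped child.
ht_join_children <- function(tree, parent, child_ids, markers,
                             label = NA_character_) {
  pid <- ht_find(tree, parent)
  child_ids <- as.integer(child_ids)
  if (length(child_ids) < 2L) stop("join needs at least two children")
  if (!all(tree$parent[child_ids] == pid))
    stop("nodes to join must all be children of the same parent")
  nid <- ht_n(tree) + 1L
  tree$parent[nid] <- pid
  tree$children[[nid]] <- integer()
  tree$markers[[nid]] <- as.character(markers)
  tree$collapsed[nid] <- 0L
  tree$label[nid] <- as.character(label)
  tree$unresolved[[nid]] <- character()
  kids <- tree$children[[pid]]
  grouped <- kids[kids %in% child_ids]     # original relative order
  slot <- match(grouped[1L], kids)
  kids <- kids[!(kids %in% child_ids)]
  kids <- append(kids, nid, after = slot - 1L)
  tree$children[[pid]] <- kids
  tree$children[[nid]] <- grouped
  tree$parent[child_ids] <- nid
  tree
}

## Remove a node; its children are spliced into its parent's child list at
## the removed node's slot. Node ids above `id` shift down by one.
ht_remove_node <- function(tree, id) {
  id <- as.integer(id)
  if (id == ht_root(tree)) stop("cannot remove the root")
  pid <- tree$parent[id]
  kids <- tree$children[[pid]]
  slot <- match(id, kids)
  own <- tree$children[[id]]
  kids <- append(kids[kids != id], own, after = slot - 1L)
  tree$children[[pid]] <- kids
  tree$parent[own] <- pid
  keep <- setdiff(seq_len(ht_n(tree)), id)
  remap <- integer(ht_n(tree)); remap[keep] <- seq_along(keep)
  tree$parent <- ifelse(is.na(tree$parent[keep]), NA_integer_,
                        remap[tree$parent[keep]])
  tree$children <- lapply(tree$children[keep],
                          function(k) remap[k])
  tree$markers <- tree$markers[keep]
  tree$collapsed <- tree$collapsed[keep]
  tree$label <- tree$label[keep]
  tree$unresolved <- tree$unresolved[keep]
  tree
}

## Detach a single marker; if it was the node's only marker, the node is
## removed (children splice upward). Returns list(tree, removed_node).
ht_detach_marker <- function(tree, marker) {
  v <- ht_node_of_marker(tree, marker)
  if (is.na(v)) stop("marker ", marker, " is not on the tree")
  cls <- tree$markers[[v]]
  if (length(cls) > 1L) {
    tree$markers[[v]] <- setdiff(cls, marker)
    list(tree = tree, removed_node = FALSE)
  } else {
    list(tree = ht_remove_node(tree, v), removed_node = TRUE)
  }
}

## Canonical form for isomorphism checks: recursively sort children by their
## canonical string; markers sorted within a class. Labels ignored.
ht_canonical <- function(tree, id = ht_root(tree)) {
  kid <- vapply(tree$children[[id]], function(c) ht_canonical(tree, c),
                character(1))
  paste0("{", paste(sort(tree$markers[[id]]), collapse = "|"),
         ":", tree$collapsed[id],
         "(", paste(sort(kid), collapse = ","), ")}")
}

#' Test two haplogroup trees for isomorphism
#'
#' Trees are isomorphic when they have the same shape with identical marker
#' equivalence classes and collapsed counts, regardless of child order and
#' labels.
#'
#' @param a,b `haplo_tree` objects.
#' @export
ht_isomorphic <- function(a, b) identical(ht_canonical(a), ht_canonical(b))

#' @export
print.haplo_tree <- function(x, max_nodes = 60L, ...) {
  cat("Haplogroup tree: ", ht_n(x), " explicit nodes, ",
      count_lineages(x), " lineages (collapsed included)\n", sep = "")
  shown <- 0L
  recurse <- function(id, depth) {
    if (shown >= max_nodes) return(invisible())
    shown <<- shown + 1L
    lab <- if (!is.na(x$label[id])) paste0(x$label[id], " ") else ""
    mk <- paste(x$markers[[id]], collapse = "/")
    col <- if (x$collapsed[id] > 0L)
      paste0(" [+", x$collapsed[id], " collapsed]") else ""
    unr <- if (length(x$unresolved[[id]]))
      paste0(" {order unresolved: ",
             paste(x$unresolved[[id]], collapse = ","), "}") else ""
    cat(strrep("  ", depth), lab,
        if (nzchar(mk)) paste0("(", mk, ")") else "(root)",
        col, unr, "\n", sep = "")
    for (c in x$children[[id]]) recurse(c, depth + 1L)
  }
  recurse(ht_root(x), 0L)
  if (shown >= max_nodes) cat("  ...\n")
  invisible(x)
}
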