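## By-lineage (YCC-style) and mutation-based haplogroup naming.
##
## Mutation-based names are "<major-clade letter>-<representative marker>"
## (E-M2). By-lineage names alternate numbers and letters by depth below the
## named root (E1b1 -> E1b1a -> E1b1a1), assigned positionally from each
## node's stored child order, which is why writers and the placement engine
## are careful never to reorder untouched siblings.

.major_letter <- function(tree) {
  lab <- tree$label[ht_root(tree)]
  if (!is.na(lab) && nzchar(lab)) substr(lab, 1L, 1L) else "?"
}

#' Mutation-based haplogroup name
#'
#' @param tree A `haplo_tree`.
#' @param node Node id, marker name, or label.
#' @param priority Optional character vector of marker names; when a node's
#'   equivalence class holds several markers the representative is the first
#'   one found in `priority`, then the first by marker-table order (see
#'   `marker_order`), then the first stored.
#' @param marker_order Optional character vector (typically
#'   `marker_table$name`) giving the default representative priority.
#' @return A string such as `"E-M2"`; the bare major-clade letter for a
#'   markerless root.
#' @export
mutation_name <- function(tree, node, priority = NULL, marker_order = NULL) {
  id <- ht_find(tree, node)
  mks <- tree$markers[[id]]
  letter <- .major_letter(tree)
  if (!length(mks)) return(letter)
  rep_marker <- NULL
  for (ord in list(priority, marker_order)) {
    if (!is.null(ord)) {
      hit <- ord[ord %in% mks]
      if (length(hit)) { rep_marker <- hit[1L]; break }
    }
  }
  if (is.null(rep_marker)) rep_marker <- mks[1L]
  paste0(letter, "-", rep_marker)
}

## number -> letter sequence a, b, ..., z, aa, ab, ... (depth letters)
.letter_seq <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

.ends_in_digit <- function(x) grepl("[0-9]$", x)

#' Hierarchical by-lineage names for every node
#'
#' The root keeps its given label; each child appends, to its parent's name,
#' its 1-based position in the stored child order, written as a number when
#' the parent's name ends in a letter and as a letter when it ends in a
#' digit (E1b1 -> E1b1a, E1b1a -> E1b1a1).
#'
#' @param tree A `haplo_tree` whose root carries a label.
#' @return A character vector of names, one per node id.
#' @export
lineage_names <- function(tree) {
  root <- ht_root(tree)
  nm <- character(ht_n(tree))
  base <- tree$label[root]
  if (is.na(base) || !nzchar(base))
    stop("the root must carry a label to seed by-lineage names")
  nm[root] <- base
  recurse <- function(id) {
    kids <- tree$children[[id]]
    for (i in seq_along(kids)) {
      tok <- if (.ends_in_digit(nm[id])) .letter_seq(i) else as.character(i)
      nm[kids[i]] <<- paste0(nm[id], tok)
      recurse(kids[i])
    }
  }
  recurse(root)
  nm
}

#' Paragroup label with exclusion notation
#'
#' Chromosomes belonging to a haplogroup but ancestral at all tested
#' downstream markers form its paragroup, written with a star and an
#' exclusion list: `E-M35*(xM78,M81,M123,V6)`.  Whitespace is normalized to
#' none.
#'
#' @param tree A `haplo_tree`.
#' @param node Node id, marker name, or label.
#' @param excluded_markers Markers tested ancestral, each of which must lie
#'   on an edge strictly below `node`.
#' @inheritParams mutation_name
#' @export
#' @examples
#' t <- haplo_tree("E", "M215")
#' t <- ht_add_child(t, "M215", "M35")
#' t <- ht_add_child(t, "M35", "M78")
#' paragroup_label(t, "M35", "M78")  # "E-M35*(xM78)"
paragroup_label <- function(tree, node, excluded_markers = character(),
                            priority = NULL, marker_order = NULL) {
  id <- ht_find(tree, node)
  excluded_markers <- as.character(excluded_markers)
  below <- setdiff(ht_descendants(tree, id), id)
  below_markers <- unlist(tree$markers[below])
  bad <- setdiff(excluded_markers, below_markers)
  if (length(bad))
    stop("excluded marker(s) not below ",
         mutation_name(tree, id, priority, marker_order), ": ",
         paste(bad, collapse = ", "))
  base <- paste0(mutation_name(tree, id, priority, marker_order), "*")
  if (!length(excluded_markers)) return(base)
  paste0(base, "(x", paste(excluded_markers, collapse = ","), ")")
}

#' Report by-lineage renames between two trees
#'
#' Nodes are matched across trees by their marker classes (any shared
#' marker) and keyed by mutation-based name, which is stable across
#' topology updates; an entry is emitted for every matched node whose
#' by-lineage name changed.
#'
#' @param old_tree,new_tree `haplo_tree` objects sharing a marker namespace.
#' @inheritParams mutation_name
#' @return A data.frame with columns `mutation_name`, `former`, `current`.
#' @export
rename_report <- function(old_tree, new_tree, priority = NULL,
                          marker_order = NULL) {
  old_nm <- lineage_names(old_tree)
  new_nm <- lineage_names(new_tree)
  out <- data.frame(mutation_name = character(), former = character(),
                    current = character(), stringsAsFactors = FALSE)
  for (v in seq_len(ht_n(new_tree))) {
    mks <- new_tree$markers[[v]]
    if (!length(mks)) next
    old_id <- NA_integer_
    for (m in mks) {
      old_id <- ht_node_of_marker(old_tree, m)
      if (!is.na(old_id)) break
    }
    if (is.na(old_id)) next
    if (!identical(old_nm[old_id], new_nm[v])) {
      out <- rbind(out, data.frame(
        mutation_name = mutation_name(new_tree, v, priority, marker_order),
        former = old_nm[old_id], current = new_nm[v],
        stringsAsFactors = FALSE))
    }
  }
  out
}
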