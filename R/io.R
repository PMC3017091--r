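## Readers and writers.  All readers reject malformed rows rather than
## coerce; all writers are deterministic byte-for-byte for a given tree
## (children are emitted in stored order, which the Newick and tabular
## formats preserve -- stored order is meaningful because by-lineage names
## are positional).

#' Read a marker table
#'
#' Expects a tab-separated file with header columns `SNP`, `Y-Position`,
#' `Mutation` (as `"<base> to <base>"`, ancestral first) and optionally
#' `Forward Primer`, `Reverse Primer`, `RefSNP ID` (`-` for none) and
#' `Reference`.  Primer columns are retained as opaque extra columns.
#'
#' @param path Path to a TSV file.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("SNP", "Y-Position", "Mutation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marker table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(marker_table(character(), numeric(), character(), character())[0, ])
  mut <- regmatches(df$Mutation,
                    regexec("^\\s*([ACGTacgt])\\s+to\\s+([ACGTacgt])\\s*$",
                            df$Mutation))
  bad <- lengths(mut) != 3L
  if (any(bad))
    stop("malformed mutation string(s): ",
         paste(df$Mutation[bad], collapse = "; "))
  anc <- vapply(mut, `[`, character(1), 2L)
  der <- vapply(mut, `[`, character(1), 3L)
  rs <- if ("RefSNP ID" %in% names(df)) df[["RefSNP ID"]] else NA_character_
  rs[rs %in% c("-", "")] <- NA_character_
  src <- if ("Reference" %in% names(df)) df$Reference else NA_character_
  out <- marker_table(df$SNP, as.numeric(df[["Y-Position"]]), anc, der,
                      rs_id = rs, source = src)
  for (col in intersect(c("Forward Primer", "Reverse Primer"), names(df)))
    out[[gsub(" ", "_", tolower(col))]] <- df[[col]]
  out
}

## state-code mapping used by the genotype TSV format
.decode_call <- function(value, marker_row) {
  if (is.na(value) || value %in% c(".", "")) return("missing")
  if (value == "0") return("ancestral")
  if (value == "1") return("derived")
  if (toupper(value) %in% c("A", "C", "G", "T"))
    return(genotype_to_state(marker_row, value))
  stop("unrecognized genotype value '", value, "' at marker ",
       marker_row$name)
}

#' Read a haploid genotype matrix
#'
#' Tab-separated: a `sample` column, optional `population` and
#' `prior_haplogroup` columns, then one column per marker holding either an
#' allele letter or a state code (`0` ancestral, `1` derived, `.` missing).
#'
#' @param path Path to a TSV file.
#' @param markers The [marker_table()] the columns must belong to.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, markers) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"sample" %in% names(df)) stop("genotype file lacks a 'sample' column")
  meta_cols <- intersect(c("sample", "population", "prior_haplogroup"),
                         names(df))
  mk_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(mk_cols, markers$name)
  if (length(unknown))
    stop("genotype file has columns for unknown markers: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  calls <- matrix("missing", nrow = nrow(df), ncol = length(mk_cols),
                  dimnames = list(df$sample, mk_cols))
  for (m in mk_cols) {
    row <- markers[markers$name == m, , drop = FALSE]
    calls[, m] <- vapply(df[[m]], .decode_call, character(1),
                         marker_row = row, USE.NAMES = FALSE)
  }
  samples <- data.frame(id = df$sample, stringsAsFactors = FALSE)
  samples$population <- if ("population" %in% names(df)) df$population
                        else NA_character_
  samples$prior_haplogroup <-
    if ("prior_haplogroup" %in% names(df)) df$prior_haplogroup
    else NA_character_
  genotype_matrix(samples, calls, markers)
}

#' Write a genotype matrix as TSV
#'
#' States are written as `0`/`1`/`.` codes so the file re-reads identically
#' regardless of marker alleles.
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes <- function(matrix, path) {
  code <- c(ancestral = "0", derived = "1", missing = ".")
  m <- matrix(code[matrix$calls], nrow = nrow(matrix$calls),
              dimnames = dimnames(matrix$calls))
  df <- data.frame(sample = matrix$samples$id,
                   population = matrix$samples$population,
                   prior_haplogroup = matrix$samples$prior_haplogroup,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

## --------------------------------------------------------------------------
## Annotated Newick dialect: node annotations ride in a bracketed comment,
## e.g.  (A,B)name[&markers=V38|V100,collapsed=6,label=E1b1].  Newick has no
## native multi-marker edge labels, so "|" separates class members.

.nwk_node <- function(tree, id) {
  kids <- tree$children[[id]]
  inner <- if (length(kids))
    paste0("(", paste(vapply(kids, function(c) .nwk_node(tree, c),
                             character(1)), collapse = ","), ")")
  else ""
  ann <- c(paste0("markers=", paste(tree$markers[[id]], collapse = "|")))
  if (tree$collapsed[id] > 0L)
    ann <- c(ann, paste0("collapsed=", tree$collapsed[id]))
  if (!is.na(tree$label[id]))
    ann <- c(ann, paste0("label=", tree$label[id]))
  if (length(tree$unresolved[[id]]))
    ann <- c(ann, paste0("unresolved=",
                         paste(tree$unresolved[[id]], collapse = "|")))
  paste0(inner, "[&", paste(ann, collapse = ","), "]")
}

#' Write a haplogroup tree
#'
#' @param tree A `haplo_tree`.
#' @param path Output path.
#' @param format `"newick"` (annotated dialect, see Details) or `"tabular"`
#'   (parent-child TSV edge list).
#' @details The Newick dialect stores each node's marker class, collapsed
#'   count and label in a `[&key=value,...]` comment, members separated by
#'   `|`.  Children are written in stored order; both formats round-trip to
#'   an identical tree including child order.
#' @export
write_tree <- function(tree, path, format = c("newick", "tabular")) {
  format <- match.arg(format)
  ht_validate(tree)
  if (format == "newick") {
    writeLines(paste0(.nwk_node(tree, ht_root(tree)), ";"), path)
  } else {
    n <- ht_n(tree)
    ord <- ht_descendants(tree, ht_root(tree))  # preorder keeps child order
    df <- data.frame(
      id = ord,
      parent = tree$parent[ord],
      markers = vapply(tree$markers[ord], paste, character(1),
                       collapse = "|"),
      collapsed = tree$collapsed[ord],
      label = tree$label[ord],
      unresolved = vapply(tree$unresolved[ord], paste, character(1),
                          collapse = "|"),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

.parse_annotation <- function(txt) {
  out <- list(markers = character(), collapsed = 0L, label = NA_character_,
              unresolved = character())
  if (!nzchar(txt)) return(out)
  for (kv in strsplit(txt, ",", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0L) stop("malformed annotation: ", kv)
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    switch(key,
      markers = { if (nzchar(val))
        out$markers <- strsplit(val, "|", fixed = TRUE)[[1L]] },
      collapsed = out$collapsed <- as.integer(val),
      label = out$label <- val,
      unresolved = out$unresolved <- strsplit(val, "|", fixed = TRUE)[[1L]],
      stop("unknown annotation key: ", key))
  }
  out
}

#' Read a haplogroup tree
#'
#' @param path Input path.
#' @param format `"newick"` or `"tabular"` (see [write_tree()]).
#' @return A `haplo_tree`.
#' @export
read_tree <- function(path, format = c("newick", "tabular")) {
  format <- match.arg(format)
  if (format == "tabular") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = "")
    if (nrow(df) == 0L) stop("empty tree file: ", path)
    # rows are in preorder; remap file ids to sequential ids
    remap <- integer(max(df$id)); remap[df$id] <- seq_len(nrow(df))
    root_row <- which(is.na(df$parent))
    if (length(root_row) != 1L) stop("tabular tree must have one root")
    split_bar <- function(x) if (is.na(x) || !nzchar(x)) character()
                             else strsplit(x, "|", fixed = TRUE)[[1L]]
    tree <- haplo_tree(as.character(df$label[root_row]),
                       split_bar(df$markers[root_row]))
    tree$collapsed[1L] <- as.integer(df$collapsed[root_row])
    tree$unresolved[[1L]] <- split_bar(df$unresolved[root_row])
    id_map <- integer(nrow(df)); id_map[root_row] <- 1L
    for (i in seq_len(nrow(df))[-root_row]) {
      tree <- ht_add_child(tree, id_map[remap[df$parent[i]]],
                           split_bar(df$markers[i]),
                           collapsed = as.integer(df$collapsed[i]),
                           label = as.character(df$label[i]))
      tree$unresolved[[ht_n(tree)]] <- split_bar(df$unresolved[i])
      id_map[i] <- ht_n(tree)
    }
    ht_validate(tree)
    return(tree)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- sub(";\\s*$", "", trimws(txt))
  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
    }
    # optional plain name, then optional [&...] annotation
    m <- regexpr("^[^,()\\[\\];]*", substr(txt, pos, n), perl = TRUE)
    pos <<- pos + attr(m, "match.length")
    ann <- list(markers = character(), collapsed = 0L,
                label = NA_character_, unresolved = character())
    if (peek() == "[") {
      close <- regexpr("]", substr(txt, pos, n), fixed = TRUE)
      if (close < 0L) stop("unterminated annotation in Newick")
      inner <- substr(txt, pos, pos + close - 2L)
      if (!startsWith(inner, "[&")) stop("malformed annotation: ", inner)
      ann <- .parse_annotation(substr(inner, 3L, nchar(inner)))
      pos <<- pos + close
    }
    list(children = kids, ann = ann)
  }
  parsed <- parse_node()
  if (pos <= n) stop("trailing characters in Newick file")
  tree <- haplo_tree(parsed$ann$label, parsed$ann$markers)
  tree$collapsed[1L] <- parsed$ann$collapsed
  tree$unresolved[[1L]] <- parsed$ann$unresolved
  attach_kids <- function(tree, node, pid) {
    for (k in node$children) {
      tree <- ht_add_child(tree, pid, k$ann$markers,
                           collapsed = k$ann$collapsed,
                           label = k$ann$label)
      nid <- ht_n(tree)
      tree$unresolved[[nid]] <- k$ann$unresolved
      tree <- attach_kids(tree, k, nid)
    }
    tree
  }
  tree <- attach_kids(tree, parsed, 1L)
  ht_validate(tree)
  tree
}

#' Write an update report
#'
#' Writes the change summary of an incremental update as YAML: lineage
#' counts before and after, one entry per placement event, and the
#' former-to-current rename map.
#'
#' @param report An `update_report` as returned by [update_tree()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  ev <- lapply(report$events, function(e) {
    list(marker = e$marker, category = e$category,
         anchors = as.list(e$anchors),
         created = isTRUE(e$created),
         recurrence = isTRUE(e$recurrence_flag),
         note = if (is.null(e$note) || is.na(e$note)) "" else e$note)
  })
  rn <- list()
  if (nrow(report$renames)) {
    for (i in seq_len(nrow(report$renames))) {
      rn[[report$renames$mutation_name[i]]] <-
        list(former = report$renames$former[i],
             current = report$renames$current[i])
    }
  }
  yaml::write_yaml(list(lineages_before = report$lineages_before,
                        lineages_after = report$lineages_after,
                        nodes_created = report$nodes_created,
                        events = ev,
                        renames = rn),
                   path)
  invisible(path)
}
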