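## End-to-end pipeline entry points: read inputs, assign, place, rename,
## write.  Configuration is a YAML key-value file; all paths are resolved
## relative to the config file's directory.

.read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  for (key in c("markers", "genotypes", "tree", "prior", "outdir"))
    cfg[[key]] <- resolve(cfg[[key]])
  cfg
}

.read_prior_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  prior_relations(df$marker, df$relation, df$target)
}

#' Run an incremental tree update from a configuration file
#'
#' The configuration names `markers` (TSV marker table), `genotypes`
#' (TSV), `tree` (reference tree file), optional `tree_format`
#' (`newick`/`tabular`), optional `new_markers` (default: every genotyped
#' marker not on the reference tree), optional `prior` (TSV with columns
#' `marker`, `relation`, `target`), optional `priority`, optional
#' `allow_incompatible` (default false) and `outdir`.  Writes
#' `updated_tree.nwk`, `report.yaml` and `assignments.tsv` into `outdir`.
#'
#' @param config Path to a YAML configuration file, or an equivalent list
#'   (with already-resolved paths).
#' @return The update result (list with `tree` and `report`), invisibly.
#' @export
run_update <- function(config) {
  cfg <- if (is.character(config)) .read_config(config) else config
  for (key in c("markers", "genotypes", "tree", "outdir"))
    if (is.null(cfg[[key]])) stop("config lacks required key: ", key)
  markers <- read_marker_table(cfg$markers)
  matrix <- read_genotypes(cfg$genotypes, markers)
  fmt <- if (is.null(cfg$tree_format)) "newick" else cfg$tree_format
  tree <- read_tree(cfg$tree, format = fmt)
  prior <- if (!is.null(cfg$prior)) .read_prior_file(cfg$prior)
  new_markers <- if (!is.null(cfg$new_markers)) unlist(cfg$new_markers)
    else setdiff(colnames(matrix$calls), unlist(tree$markers))
  res <- update_tree(tree, matrix, new_markers, prior = prior,
                     priority = unlist(cfg$priority))
  bad <- vapply(res$report$events, function(e)
    e$category == "unplaced_incompatible", logical(1))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tree(res$tree, file.path(cfg$outdir, "updated_tree.nwk"), "newick")
  write_report(res$report, file.path(cfg$outdir, "report.yaml"))
  utils::write.table(res$report$assignments,
                     file.path(cfg$outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(bad) && !isTRUE(cfg$allow_incompatible)) {
    offenders <- vapply(res$report$events[bad], `[[`, character(1), "marker")
    cond <- structure(
      class = c("haplotree_incompatible", "error", "condition"),
      list(message = paste0("unplaceable marker(s): ",
                            paste(offenders, collapse = ", "),
                            " (outputs written to ", cfg$outdir, ")"),
           call = NULL))
    stop(cond)
  }
  invisible(res)
}

#' Run the bundled E1b1 case-study update
#'
#' Convenience wrapper: updates the pre-revision E1b1 reference tree with
#' the twelve newly characterized markers (and the re-genotyped M154 and
#' M281) against the 174-sample panel.
#'
#' @param outdir Optional output directory for the tree/report files.
#' @return A list with `tree` and `report` (see [update_tree()]).
#' @export
run_e1b1_update <- function(outdir = NULL) {
  fx <- e1b1_fixture()
  res <- update_tree(fx$tree, fx$genotypes, fx$new_markers,
                     prior = fx$prior, priority = fx$priority)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tree(res$tree, file.path(outdir, "updated_tree.nwk"), "newick")
    write_report(res$report, file.path(outdir, "report.yaml"))
    utils::write.table(res$report$assignments,
                       file.path(outdir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

## write a marker table back out in the tabular dialect
write_marker_table <- function(markers, path) {
  df <- data.frame(
    SNP = markers$name,
    `Y-Position` = format(markers$position, scientific = FALSE,
                          trim = TRUE),
    Mutation = paste(markers$ancestral, "to", markers$derived),
    `RefSNP ID` = ifelse(is.na(markers$rs_id), "-", markers$rs_id),
    Reference = markers$source,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a panel to files
#'
#' Reads a YAML configuration with the [sim_config()] fields plus
#' `outdir`; writes `truth_tree.nwk`, `markers.tsv`, `genotypes.tsv` and
#' `truth_assignments.tsv`.  Output is byte-identical for a fixed seed.
#'
#' @param config Path to a YAML file or an equivalent list.
#' @return Invisibly, a list with the simulated `tree`, `matrix`, `truth`.
#' @export
run_simulation <- function(config) {
  cfg <- if (is.character(config)) .read_config(config) else config
  if (is.null(cfg$outdir)) stop("config lacks required key: outdir")
  sc <- sim_config(
    n_leaves = if (is.null(cfg$n_leaves)) 8L else cfg$n_leaves,
    mean_mutations_per_branch =
      if (is.null(cfg$mean_mutations_per_branch)) 2
      else cfg$mean_mutations_per_branch,
    samples_per_node = if (is.null(cfg$samples_per_node)) 2L
      else cfg$samples_per_node,
    missing_rate = if (is.null(cfg$missing_rate)) 0 else cfg$missing_rate,
    recurrence_rate = if (is.null(cfg$recurrence_rate)) 0
      else cfg$recurrence_rate,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  tree <- simulate_tree(sc)
  sim <- simulate_genotypes(tree, sc)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tree(tree, file.path(cfg$outdir, "truth_tree.nwk"), "newick")
  write_marker_table(sim$matrix$markers,
                     file.path(cfg$outdir, "markers.tsv"))
  write_genotypes(sim$matrix, file.path(cfg$outdir, "genotypes.tsv"))
  utils::write.table(sim$truth,
                     file.path(cfg$outdir, "truth_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(tree = tree, matrix = sim$matrix, truth = sim$truth))
}

#' Compare a de-novo reconstruction against a truth tree
#'
#' Rebuilds the tree from a genotype file by perfect phylogeny and reports
#' whether it is isomorphic to the truth (identical marker classes and
#' shape), listing unplaced markers and unresolved-order classes.
#'
#' @param genotypes,markers,truth_tree File paths (genotype TSV, marker
#'   TSV, truth tree Newick).
#' @return A list with `verdict` (`"exact"` or `"different"`),
#'   `unplaced`, `unresolved` and the reconstructed `tree`.
#' @export
run_recovery <- function(genotypes, markers, truth_tree) {
  mt <- read_marker_table(markers)
  gm <- read_genotypes(genotypes, mt)
  truth <- read_tree(truth_tree, "newick")
  built <- build_perfect_phylogeny(gm, root_label = truth$label[1L])
  list(verdict = if (ht_isomorphic(built, truth)) "exact" else "different",
       unplaced = attr(built, "unplaced"),
       unresolved = unique(unlist(built$unresolved)),
       tree = built)
}
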