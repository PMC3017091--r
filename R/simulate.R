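## Seeded simulation of haplogroup trees and genotype panels with known
## truth.  The generator emulates the evidence structure of a binary-marker
## survey: haploid samples sit at every node of a rooted tree (internal
## nodes hold paragroup samples), each branch carries one or more unique
## mutations, and noise enters as i.i.d. missing calls and optional
## recurrent mutations that strike a second, independently chosen branch.

#' Simulation configuration
#'
#' @param n_leaves Number of leaves of the truth tree (>= 2).
#' @param mean_mutations_per_branch Poisson mean for mutations drawn per
#'   branch; branches drawing zero are contracted, so retained branches
#'   carry a zero-truncated Poisson number of markers.
#' @param samples_per_node Samples attached to every node (root and
#'   internal nodes included), a single integer.
#' @param missing_rate Probability that any single call is missing.
#' @param recurrence_rate Probability that a marker also mutates on a
#'   second, independently chosen branch.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_leaves = 8L, mean_mutations_per_branch = 2,
                       samples_per_node = 2L, missing_rate = 0,
                       recurrence_rate = 0, seed = 1L) {
  stopifnot(n_leaves >= 2L, mean_mutations_per_branch > 0,
            samples_per_node >= 0L,
            missing_rate >= 0, missing_rate <= 1,
            recurrence_rate >= 0, recurrence_rate <= 1,
            abs(seed) < 2^31 - 2)
  structure(list(n_leaves = as.integer(n_leaves),
                 mean_mutations_per_branch = mean_mutations_per_branch,
                 samples_per_node = as.integer(samples_per_node),
                 missing_rate = missing_rate,
                 recurrence_rate = recurrence_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## evaluate expr under a local RNG stream, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a truth haplogroup tree
#'
#' Topology grows by uniform attachment (each new branch attaches to a
#' uniformly chosen existing node) until the requested number of leaves is
#' reached.  Each branch draws a Poisson number of mutations; zero-mutation
#' branches are contracted, so every retained branch carries at least one
#' synthetic marker (`S001`, `S002`, ... in preorder).  Markers selected
#' for recurrence are listed in `attr(tree, "recurrent")` together with the
#' second struck branch.
#'
#' @param config A [sim_config()].
#' @return A `haplo_tree` with attributes `recurrent` (data.frame
#'   `marker`/`second_node`) for downstream genotype simulation.
#' @export
simulate_tree <- function(config) {
  .with_seed(config$seed, {
    parent <- c(NA_integer_)
    is_leaf <- logical(1)  # root is not a leaf
    n_leaves <- 0L
    while (n_leaves < config$n_leaves) {
      host <- sample.int(length(parent), 1L)
      if (is_leaf[host]) { is_leaf[host] <- FALSE; n_leaves <- n_leaves - 1L }
      parent <- c(parent, host)
      is_leaf <- c(is_leaf, TRUE)
      n_leaves <- n_leaves + 1L
    }
    # mutations per branch; zero-mutation internal branches are contracted,
    # leaf branches draw a zero-truncated count so every requested leaf is
    # realized -- retained branches therefore all carry >= 1 marker and
    # their counts follow a zero-truncated Poisson
    counts <- stats::rpois(length(parent), config$mean_mutations_per_branch)
    counts[1L] <- 0L
    for (v in seq_along(parent)[-1L]) {
      if (is_leaf[v]) {
        while (counts[v] == 0L)
          counts[v] <- stats::rpois(1L, config$mean_mutations_per_branch)
      }
    }
    for (v in rev(seq_along(parent))) {
      if (v == 1L || counts[v] > 0L) next
      kids <- which(parent == v)
      parent[kids] <- parent[v]
      parent[v] <- -1L  # tombstone
    }
    keep <- setdiff(seq_along(parent), which(parent == -1L))
    remap <- integer(length(parent)); remap[keep] <- seq_along(keep)
    parent <- ifelse(is.na(parent[keep]), NA_integer_, remap[parent[keep]])
    counts <- counts[keep]
    # assemble the haplo_tree (ancestors precede descendants, so children
    # are appended in a deterministic order)
    tree <- haplo_tree("R")
    id_map <- integer(length(parent)); id_map[1L] <- 1L
    total <- 0L
    next_marker <- function(k) {
      out <- sprintf("S%03d", total + seq_len(k)); total <<- total + k; out
    }
    for (v in seq_along(parent)[-1L]) {
      mks <- next_marker(counts[v])
      tree <- ht_add_child(tree, id_map[parent[v]], mks)
      id_map[v] <- ht_n(tree)
    }
    ht_validate(tree)
    markers <- unlist(tree$markers)
    rec <- stats::runif(length(markers)) < config$recurrence_rate
    second <- integer(0); recm <- character(0)
    if (any(rec) && ht_n(tree) > 2L) {
      for (m in markers[rec]) {
        own <- ht_node_of_marker(tree, m)
        pool <- setdiff(seq_len(ht_n(tree))[-1L],
                        c(ht_descendants(tree, own),
                          ht_path_to_root(tree, own)))
        if (!length(pool)) next
        recm <- c(recm, m)
        second <- c(second, if (length(pool) == 1L) pool
                   else sample(pool, 1L))
      }
    }
    attr(tree, "recurrent") <- data.frame(marker = recm,
                                          second_node = second,
                                          stringsAsFactors = FALSE)
    tree
  })
}

#' Simulate a genotype panel on a truth tree
#'
#' Attaches `samples_per_node` samples to every node; a sample is derived
#' at every marker on its root path (plus any recurrent marker striking a
#' second branch above it) and ancestral elsewhere, after which missing
#' calls are applied i.i.d.  Sample ids are deterministic
#' (`n<node>_s<index>`).
#'
#' @param tree A tree from [simulate_tree()] (or hand built; recurrence is
#'   honoured when `attr(tree, "recurrent")` is present).
#' @param config The same [sim_config()].
#' @return A list with `matrix` (a [genotype_matrix()]) and `truth` (a
#'   data.frame `sample`/`node_id` of true attachment points).
#' @export
simulate_genotypes <- function(tree, config) {
  .with_seed(config$seed + 1L, {
    markers <- unlist(tree$markers)
    mt <- marker_table(markers, seq_along(markers) * 1000, "C", "T",
                       source = "simulated")
    n <- ht_n(tree)
    k <- config$samples_per_node
    ids <- character(0); node_of <- integer(0)
    for (v in seq_len(n)) {
      if (k > 0L) {
        ids <- c(ids, sprintf("n%03d_s%d", v, seq_len(k)))
        node_of <- c(node_of, rep(v, k))
      }
    }
    calls <- matrix("ancestral", nrow = length(ids), ncol = length(markers),
                    dimnames = list(ids, markers))
    rec <- attr(tree, "recurrent")
    for (i in seq_along(ids)) {
      path <- ht_path_to_root(tree, node_of[i])
      calls[i, unlist(tree$markers[path])] <- "derived"
    }
    if (!is.null(rec) && nrow(rec)) {
      for (r in seq_len(nrow(rec))) {
        below <- ht_descendants(tree, rec$second_node[r])
        calls[node_of %in% below, rec$marker[r]] <- "derived"
      }
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(calls)) < config$missing_rate
      calls[drop] <- "missing"
    }
    samples <- data.frame(id = ids, population = NA_character_,
                          prior_haplogroup = NA_character_,
                          stringsAsFactors = FALSE)
    list(matrix = genotype_matrix(samples, calls, mt),
         truth = data.frame(sample = ids, node_id = node_of,
                            stringsAsFactors = FALSE))
  })
}
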