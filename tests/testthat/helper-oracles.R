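# Shared fixtures and independent oracles used across the suite.

# order-sensitive tree signature (child order matters, node ids do not)
ordered_sig <- function(tree, id = 1L) {
  kids <- tree$children[[id]]
  paste0("{", paste(tree$markers[[id]], collapse = "|"), ":",
         tree$collapsed[id],
         "(", paste(vapply(kids, function(c) ordered_sig(tree, c),
                           character(1)), collapse = ","), ")}")
}

# genotype_matrix from a compact character matrix of "0"/"1"/"." codes
gm_from_codes <- function(codes) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  map <- c("0" = "ancestral", "1" = "derived", "." = "missing")
  calls <- matrix(map[codes], nrow = nrow(codes),
                  dimnames = dimnames(codes))
  mt <- marker_table(colnames(codes), seq_len(ncol(codes)) * 100, "C", "T")
  genotype_matrix(data.frame(id = rownames(codes)), calls, mt)
}

# Exhaustive oracle for joint tree-compatibility of binary characters with
# known ancestral states: enumerate every rooted forest over the markers
# (parent function into markers + root) and ask whether every sample can
# sit at some node, i.e. its observed derived set is exactly contained in
# that node's root path and no observed ancestral marker lies on the path.
# Bitmask arithmetic keeps full enumeration cheap for <= 4 markers.
oracle_forest_masks <- function(m) {
  opts <- lapply(seq_len(m), function(i) setdiff(0:m, i))
  grid <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(grid[r, ])
    masks <- integer(m); ok <- TRUE
    for (x in seq_len(m)) {
      seen <- integer(); v <- x
      while (v != 0L) {
        if (v %in% seen) { ok <- FALSE; break }
        seen <- c(seen, v); v <- p[v]
      }
      if (!ok) break
      masks[x] <- sum(bitwShiftL(1L, seen - 1L))
    }
    if (ok) out[[length(out) + 1L]] <- c(0L, masks)  # 0 = root position
  }
  unique(out)
}

oracle_compatible <- function(calls, forests = NULL) {
  m <- ncol(calls)
  if (is.null(forests)) forests <- oracle_forest_masks(m)
  dmask <- apply(calls == "derived", 1, function(z)
    sum(bitwShiftL(1L, which(z) - 1L)))
  amask <- apply(calls == "ancestral", 1, function(z)
    sum(bitwShiftL(1L, which(z) - 1L)))
  for (f in forests) {
    ok <- TRUE
    for (s in seq_along(dmask)) {
      if (!any(bitwAnd(dmask[s], f) == dmask[s] & bitwAnd(amask[s], f) == 0L)) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# small hand-built tree used by several placement/nomenclature tests:
#  E (root) -> M215 -> M35 -> {M78, M81}
small_m35_tree <- function() {
  t <- haplo_tree("E", "P2")
  t <- ht_add_child(t, "E", "M215")
  t <- ht_add_child(t, "M215", "M35")
  t <- ht_add_child(t, "M35", "M78")
  t <- ht_add_child(t, "M35", "M81")
  t
}
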