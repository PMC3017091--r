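test_that("carrier_set collects exactly the observed derived samples", {
  gm <- gm_from_codes(rbind(s1 = c(A = "1", B = "0"),
                            s2 = c(A = ".", B = "0"),
                            s3 = c(A = "1", B = "1")))
  cs <- carrier_set(gm, "A")
  expect_setequal(cs$carriers, c("s1", "s3"))
  expect_setequal(cs$ancestral, character(0))
  expect_error(carrier_set(gm, "Z"), "unknown marker")
  # all-ancestral column gives the empty set
  expect_length(carrier_set(gm, "B")$carriers, 1L)

  # fixture: the nine M154 carriers sit in the E-U209* panel
  g <- e1b1_genotypes()
  expect_length(carrier_set(g, "M154")$carriers, 9L)

  # random matrices agree with an independent cell-by-cell scan
  for (seed in 1:5) {
    sim <- simulate_genotypes(simulate_tree(sim_config(seed = seed)),
                              sim_config(seed = seed, missing_rate = 0.3))
    for (m in colnames(sim$matrix$calls)) {
      scan <- character()
      for (s in rownames(sim$matrix$calls))
        if (sim$matrix$calls[s, m] == "derived") scan <- c(scan, s)
      expect_setequal(carrier_set(sim$matrix, m)$carriers, scan)
    }
  }
})

test_that("check_compatibility flags overlap without nesting", {
  gm <- gm_from_codes(rbind(a = c(X = "1", Y = "1"),
                            b = c(X = "1", Y = "0"),
                            c = c(X = "0", Y = "1")))
  chk <- check_compatibility(carrier_sets(gm))
  expect_false(chk$compatible)
  expect_setequal(unname(unlist(chk$violations[1, ])), c("X", "Y"))

  # nested sets are compatible
  gm2 <- gm_from_codes(rbind(a = c(X = "1", Y = "1"),
                             b = c(X = "1", Y = "1"),
                             c = c(X = "1", Y = "0")))
  expect_true(check_compatibility(carrier_sets(gm2))$compatible)

  # missing calls never witness a violation
  gm3 <- gm_from_codes(rbind(a = c(X = "1", Y = "1"),
                             b = c(X = "1", Y = "."),
                             c = c(X = ".", Y = "1")))
  expect_true(check_compatibility(carrier_sets(gm3))$compatible)
})

test_that("find_equivalent recovers classes planted by column duplication", {
  gm <- e1b1_genotypes()
  eq <- find_equivalent(gm, c("M2", "V43", "V95", "U209", "M154"))
  cls <- eq$classes[[which(vapply(eq$classes, function(k) "M2" %in% k,
                                  logical(1)))]]
  expect_setequal(cls, c("M2", "V43", "V95"))

  # all-distinct columns give singletons
  gm2 <- gm_from_codes(rbind(c(A = "1", B = "1", C = "0"),
                             c(A = "1", B = "0", C = "0"),
                             c(A = "0", B = "0", C = "1")))
  expect_true(all(lengths(find_equivalent(gm2)$classes) == 1L))

  # duplicating random columns is recovered exactly, unflagged
  for (seed in 1:5) {
    sim <- simulate_genotypes(simulate_tree(sim_config(seed = seed)),
                              sim_config(seed = seed))
    base <- sim$matrix$calls
    dup <- cbind(base, DUP1 = base[, 1L], DUP2 = base[, 1L])
    mt <- marker_table(colnames(dup), seq_len(ncol(dup)), "C", "T")
    gm3 <- genotype_matrix(sim$matrix$samples, dup, mt)
    eq3 <- find_equivalent(gm3)
    k <- which(vapply(eq3$classes, function(x) "DUP1" %in% x, logical(1)))
    expect_true(all(c(colnames(base)[1L], "DUP1", "DUP2") %in%
                      eq3$classes[[k]]))
    expect_false(eq3$ambiguous[k])
  }
})

test_that("build_perfect_phylogeny forces a chain on nested carriers", {
  gm <- gm_from_codes(rbind(a = c(X = "1", Y = "1", Z = "1"),
                            b = c(X = "1", Y = "1", Z = "0"),
                            c = c(X = "1", Y = "0", Z = "0"),
                            d = c(X = "1", Y = "0", Z = "0")))
  tr <- build_perfect_phylogeny(gm)
  expect_equal(count_lineages(tr), 4L)  # root + chain of three
  z <- ht_node_of_marker(tr, "Z"); y <- ht_node_of_marker(tr, "Y")
  x <- ht_node_of_marker(tr, "X")
  expect_identical(tr$parent[z], y)
  expect_identical(tr$parent[y], x)
})

test_that("incompatible matrices raise a typed error naming the pairs", {
  gm <- gm_from_codes(rbind(a = c(X = "1", Y = "1"),
                            b = c(X = "1", Y = "0"),
                            c = c(X = "0", Y = "1")))
  err <- tryCatch(build_perfect_phylogeny(gm), error = identity)
  expect_s3_class(err, "haplotree_incompatible")
  expect_true(all(c("X", "Y") %in% unlist(err$violations)))
})

test_that("zero-carrier markers are retained but left unplaced", {
  gm <- gm_from_codes(rbind(a = c(X = "1", Y = "0"),
                            b = c(X = "1", Y = "0")))
  tr <- build_perfect_phylogeny(gm)
  expect_identical(attr(tr, "unplaced"), "Y")
  expect_true(is.na(ht_node_of_marker(tr, "Y")))
})

test_that("every edge clade equals its input carrier set on laminar data", {
  for (seed in 1:10) {
    cfg <- sim_config(n_leaves = 8, samples_per_node = 2, seed = seed)
    sim <- simulate_genotypes(simulate_tree(cfg), cfg)
    tr <- build_perfect_phylogeny(sim$matrix, "R")
    asg <- assign_samples(tr, sim$matrix)
    for (m in colnames(sim$matrix$calls)) {
      v <- ht_node_of_marker(tr, m)
      clade_ids <- which(asg$node_id %in%
                           haplotree:::ht_descendants(tr, v))
      expect_setequal(asg$sample[clade_ids],
                      carrier_set(sim$matrix, m)$carriers)
    }
  }
})

test_that("removing a marker column never makes a compatible matrix
           incompatible", {
  for (seed in 1:8) {
    cfg <- sim_config(n_leaves = 6, seed = seed)
    sim <- simulate_genotypes(simulate_tree(cfg),
                              sim_config(n_leaves = 6, seed = seed,
                                         missing_rate = 0.15))
    sets <- carrier_sets(sim$matrix)
    if (!check_compatibility(sets)$compatible) next
    for (drop in seq_along(sets))
      expect_true(check_compatibility(sets[-drop])$compatible)
  }
})

test_that("empty-residual nestings merge onto one edge flagged unresolved", {
  # B's carriers are a strict subset of A's, but the residual sample is
  # missing at B: no observation separates the classes
  gm <- gm_from_codes(rbind(a = c(A = "1", B = "1"),
                            b = c(A = "1", B = "."),
                            c = c(A = "0", B = "0")))
  tr <- build_perfect_phylogeny(gm)
  v <- ht_node_of_marker(tr, "A")
  expect_identical(v, ht_node_of_marker(tr, "B"))
  expect_true("B" %in% unlist(tr$unresolved))
})
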