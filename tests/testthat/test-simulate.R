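test_that("simulation is byte-deterministic for a fixed seed", {
  cfg <- sim_config(n_leaves = 10, samples_per_node = 2,
                    missing_rate = 0.1, recurrence_rate = 0.1, seed = 42)
  t1 <- simulate_tree(cfg); t2 <- simulate_tree(cfg)
  expect_identical(ordered_sig(t1), ordered_sig(t2))
  expect_identical(attr(t1, "recurrent"), attr(t2, "recurrent"))
  g1 <- simulate_genotypes(t1, cfg); g2 <- simulate_genotypes(t2, cfg)
  expect_identical(g1$matrix$calls, g2$matrix$calls)
  expect_identical(g1$truth, g2$truth)
  # and file output is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulation(c(unclass(cfg), list(outdir = d1)))
  run_simulation(c(unclass(cfg), list(outdir = d2)))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("simulate_tree leaves no global RNG footprint", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_tree(sim_config(seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_leaves = 1))
  expect_error(sim_config(missing_rate = 1.5))
  expect_error(sim_config(recurrence_rate = -0.1))
  expect_error(sim_config(mean_mutations_per_branch = 0))
})

test_that("marker totals follow the zero-truncated Poisson expectation", {
  # retained branches carry ZTP(lambda) markers; on a large tree the total
  # should fall within 3 sigma of the analytic mean
  lambda <- 3
  cfg <- sim_config(n_leaves = 120, mean_mutations_per_branch = lambda,
                    samples_per_node = 0, seed = 31)
  tr <- simulate_tree(cfg)
  b <- length(tr$parent) - 1L            # retained branches
  total <- length(unlist(tr$markers))
  mu <- lambda / (1 - exp(-lambda))
  sigma2 <- mu * (1 + lambda - mu)       # ZTP variance
  expect_lt(abs(total - b * mu), 3 * sqrt(b * sigma2))
  expect_true(all(lengths(tr$markers)[-1L] >= 1L))
})

test_that("a two-leaf tree has at least three lineages", {
  tr <- simulate_tree(sim_config(n_leaves = 2, seed = 5))
  expect_gte(count_lineages(tr), 3L)
})

test_that("noise-free panels rebuild the truth tree exactly", {
  for (seed in 1:15) {
    cfg <- sim_config(n_leaves = 4 + (seed %% 12), samples_per_node = 2,
                      seed = seed)
    tr <- simulate_tree(cfg)
    sim <- simulate_genotypes(tr, cfg)
    expect_true(ht_isomorphic(build_perfect_phylogeny(sim$matrix, "R"), tr))
  }
})

test_that("fully missing panels place nothing", {
  cfg <- sim_config(n_leaves = 5, samples_per_node = 2, missing_rate = 1,
                    seed = 2)
  tr <- simulate_tree(cfg)
  sim <- simulate_genotypes(tr, cfg)
  built <- build_perfect_phylogeny(sim$matrix, "R")
  expect_identical(length(built$parent), 1L)
  expect_setequal(attr(built, "unplaced"), unlist(tr$markers))
})

test_that("planted recurrent markers are named in violating pairs", {
  cfg <- sim_config(n_leaves = 10, samples_per_node = 3,
                    recurrence_rate = 0.25, seed = 11)
  tr <- simulate_tree(cfg)
  rec <- attr(tr, "recurrent")
  expect_gt(nrow(rec), 0L)
  sim <- simulate_genotypes(tr, cfg)
  chk <- check_compatibility(carrier_sets(sim$matrix))
  expect_false(chk$compatible)
  expect_true(all(rec$marker %in% unlist(chk$violations)))
})

test_that("moderate missingness merges classes but does not misplace
           markers", {
  # with missing calls a marker may become indistinguishable from its
  # neighbour on the same root path (merged, flagged unresolved), but a
  # placed marker must never end up on an edge incompatible with truth
  for (seed in 1:20) {
    cfg <- sim_config(n_leaves = 10, samples_per_node = 3,
                      mean_mutations_per_branch = 2,
                      missing_rate = 0.1, seed = seed)
    tr <- simulate_tree(cfg)
    sim <- simulate_genotypes(tr, cfg)
    built <- build_perfect_phylogeny(sim$matrix, "R")
    # for every pair of markers on one built edge, the pair must be
    # path-comparable in the truth tree (same root path)
    for (v in seq_along(built$parent)[-1L]) {
      mks <- built$markers[[v]]
      true_nodes <- unique(vapply(mks, function(m)
        haplotree:::ht_node_of_marker(tr, m), integer(1)))
      for (a in true_nodes) for (b in true_nodes)
        expect_true(haplotree:::ht_is_ancestor(tr, a, b) ||
                      haplotree:::ht_is_ancestor(tr, b, a))
    }
    # and parent/child order of built edges never contradicts truth
    for (v in seq_along(built$parent)[-1L]) {
      p <- built$parent[v]
      if (p == 1L) next
      m_child <- built$markers[[v]][1L]
      m_par <- built$markers[[p]][1L]
      a <- haplotree:::ht_node_of_marker(tr, m_par)
      b <- haplotree:::ht_node_of_marker(tr, m_child)
      expect_true(haplotree:::ht_is_ancestor(tr, a, b))
    }
  }
})
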