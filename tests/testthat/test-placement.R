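test_that("assign_samples finds deepest nodes, paragroups and exclusions", {
  fx <- e1b1_fixture()
  # M154 and M281 are on the reference tree, so only the twelve genuinely
  # new markers are masked here
  asg <- assign_samples(fx$tree, fx$genotypes,
                        exclude = setdiff(fx$new_markers, c("M154", "M281")))
  g <- fx$genotypes

  # an E-M35* chromosome: derived at M215/M35, ancestral at the four
  # tested child edges -> paragroup with the printed exclusion list
  row <- asg[asg$sample == "EM35x_001", ]
  expect_identical(row$haplogroup, "E-M35")
  expect_true(row$is_paragroup)
  expect_setequal(strsplit(row$excluded, ",")[[1L]],
                  c("M78", "M81", "M123", "M281", "V6"))

  # derived at a marker whose stored edge contradicts an ancestral call
  # upstream: assigned to the deepest consistent node, conflict flagged
  row2 <- asg[asg$sample == "EM215x_001", ]
  expect_identical(row2$haplogroup, "E-M215")
  expect_true(row2$conflict)
  expect_match(row2$note, "M281")

  # samples derived at markers of two sibling clades are flagged
  mt <- fx$markers
  calls <- matrix("ancestral", 1, 3,
                  dimnames = list("bad", c("M2", "M215", "M35")))
  calls[1, ] <- "derived"   # M2 and M215 are incomparable
  gm <- genotype_matrix(data.frame(id = "bad"), calls, mt)
  a2 <- assign_samples(fx$tree, gm)
  expect_true(a2$conflict[1L])
  expect_match(a2$note[1L], "incomparable")

  # a genotyped marker neither on the tree nor excluded is an error
  expect_error(assign_samples(fx$tree, fx$genotypes), "neither on the tree")
})

test_that("assign_samples matches generator truth on simulated panels", {
  for (seed in 1:5) {
    cfg <- sim_config(n_leaves = 8, samples_per_node = 2, seed = seed)
    tr <- simulate_tree(cfg)
    sim <- simulate_genotypes(tr, cfg)
    asg <- assign_samples(tr, sim$matrix)
    expect_identical(asg$node_id[match(sim$truth$sample, asg$sample)],
                     sim$truth$node_id)
    expect_false(any(asg$conflict))
  }
})

test_that("place_marker categorizes events by carrier-set relations", {
  fx <- e1b1_fixture()
  tr <- fx$tree
  gm <- fx$genotypes
  asg <- assign_samples(tr, gm, exclude = fx$new_markers)

  # join: V100 carriers cover all of E-M2 plus (by prior report) E-M329
  st <- place_marker(tr, "V100", carrier_set(gm, "V100"), asg,
                     prior = fx$prior, matrix = gm)
  expect_identical(st$event$category, "join_clades")
  expect_setequal(st$event$anchors, c("E-M2", "E-M329"))
  v100 <- ht_node_of_marker(st$tree, "V100")
  expect_identical(st$tree$parent[v100], 1L)
  expect_length(st$tree$children[[1L]], 2L)

  # equivalent: V38 carriers equal the new node's clade and the prior
  # relation to M329 picks the joined edge, not E-M2
  asg2 <- assign_samples(st$tree, gm,
                         exclude = setdiff(fx$new_markers, "V100"))
  st2 <- place_marker(st$tree, "V38", carrier_set(gm, "V38"), asg2,
                      prior = fx$prior, matrix = gm)
  expect_identical(st2$event$category, "equivalent")
  expect_identical(ht_node_of_marker(st2$tree, "V38"), v100)
  expect_false(st2$event$created)

  # V43 is instead equivalent to E-M2 itself (prior: disjoint from M329)
  st3 <- place_marker(st2$tree, "V43", carrier_set(gm, "V43"),
                      assign_samples(st2$tree, gm,
                                     exclude = setdiff(fx$new_markers,
                                                       c("V100", "V38"))),
                      prior = fx$prior, matrix = gm)
  expect_identical(ht_node_of_marker(st3$tree, "V43"),
                   ht_node_of_marker(st3$tree, "M2"))

  # split_paragroup: V39 carriers sit inside the E-U209 paragroup
  st4 <- place_marker(tr, "V39", carrier_set(gm, "V39"), asg,
                      prior = fx$prior, matrix = gm)
  expect_identical(st4$event$category, "split_paragroup")
  expect_identical(st4$event$anchors, "E-U209")

  # insert_above: M293 carriers are E-M35 paragroup samples plus the
  # (previously reported) P72 clade
  st5 <- place_marker(tr, "M293", carrier_set(gm, "M293"), asg,
                      prior = fx$prior, matrix = gm)
  expect_identical(st5$event$category, "insert_above")
  expect_identical(st5$event$anchors, "E-P72")
  p72 <- ht_node_of_marker(st5$tree, "P72")
  expect_identical(st5$tree$parent[p72], ht_node_of_marker(st5$tree, "M293"))

  # empty carrier set: unplaced, not an error
  mt2 <- rbind(fx$markers,
               marker_table("NEWX", 99, "C", "T"))
  calls2 <- cbind(gm$calls, NEWX = "ancestral")
  gm2 <- genotype_matrix(gm$samples, calls2, mt2)
  st6 <- place_marker(tr, "NEWX", carrier_set(gm2, "NEWX"), asg)
  expect_identical(st6$event$category, "unplaced_no_carriers")

  # overlap without nesting: unplaced_incompatible
  calls3 <- cbind(gm$calls, NEWX = "ancestral")
  calls3[c("EM2x_001", "EM215x_002"), "NEWX"] <- "derived"
  gm3 <- genotype_matrix(gm$samples, calls3, mt2)
  asg3 <- assign_samples(tr, gm3, exclude = c(fx$new_markers, "NEWX"))
  st7 <- place_marker(tr, "NEWX", carrier_set(gm3, "NEWX"), asg3)
  expect_identical(st7$event$category, "unplaced_incompatible")
})

test_that("collapsed subtrees are opaque to placement", {
  fx <- e1b1_fixture()
  gm <- fx$genotypes
  # a marker derived in a strict subset of the (sample-free) E-M78 clade
  # cannot be placed without expanding the collapsed subtree; simulate by
  # giving M78's node samples and aiming below it
  mt2 <- rbind(fx$markers, marker_table("NEWX", 99, "C", "T"))
  calls2 <- cbind(gm$calls, NEWX = "ancestral")
  calls2["EM78_001", "NEWX"] <- "derived"   # inside E-M78, which is collapsed
  gm2 <- genotype_matrix(gm$samples, calls2, mt2)
  asg <- assign_samples(fx$tree, gm2, exclude = c(fx$new_markers, "NEWX"))
  expect_error(
    place_marker(fx$tree, "NEWX", carrier_set(gm2, "NEWX"), asg,
                 matrix = gm2),
    "collapsed subtree")
})

test_that("detect_recurrence repositions markers contradicted by carriers", {
  fx <- e1b1_fixture()
  st <- detect_recurrence(fx$tree, "M154", carrier_set(fx$genotypes, "M154"),
                          fx$genotypes, prior = fx$prior,
                          exclude = setdiff(fx$new_markers, "M154"))
  expect_identical(st$event$category, "reposition")
  expect_true(st$event$recurrence_flag)
  m154 <- ht_node_of_marker(st$tree, "M154")
  expect_identical(st$tree$parent[m154], ht_node_of_marker(st$tree, "U209"))
  expect_identical(st$event$net_created, 0L)

  # a marker whose carriers match its stored clade yields no event
  st2 <- detect_recurrence(st$tree, "M154",
                           carrier_set(fx$genotypes, "M154"),
                           fx$genotypes, prior = fx$prior,
                           exclude = setdiff(fx$new_markers, "M154"))
  expect_identical(st2$event$category, "consistent")
  expect_false(st2$event$recurrence_flag)

  # a genuinely recurrent simulated marker stays unplaced_incompatible
  cfg <- sim_config(n_leaves = 8, samples_per_node = 2, seed = 5)
  tr <- simulate_tree(cfg)
  sim <- simulate_genotypes(tr, cfg)
  m <- tr$markers[[3L]][1L]
  calls <- sim$matrix$calls
  other <- setdiff(seq_len(length(tr$parent))[-1L],
                   c(haplotree:::ht_descendants(tr, 3L),
                     haplotree:::ht_path_to_root(tr, 3L)))
  # strike a non-basal branch: a second origin inside another subtree is
  # not explainable as a clade join, so it must stay unplaceable
  other <- other[tr$parent[other] != 1L]
  below <- haplotree:::ht_descendants(tr, other[1L])
  hit <- sim$truth$sample[sim$truth$node_id %in% below]
  calls[hit, m] <- "derived"   # plant a second origin
  gm <- genotype_matrix(sim$matrix$samples, calls, sim$matrix$markers)
  st3 <- detect_recurrence(tr, m, carrier_set(gm, m), gm)
  expect_identical(st3$event$category, "unplaced_incompatible")
  expect_identical(ordered_sig(st3$tree), ordered_sig(tr))  # untouched
})

test_that("update_tree is idempotent and conserves sample assignments", {
  fx <- e1b1_fixture()
  res <- update_tree(fx$tree, fx$genotypes, fx$new_markers,
                     prior = fx$prior, priority = fx$priority)
  expect_equal(res$report$lineages_after - res$report$lineages_before,
               res$report$nodes_created)

  # idempotence: a second run creates nothing and changes nothing
  res2 <- update_tree(res$tree, fx$genotypes, fx$new_markers,
                      prior = fx$prior, priority = fx$priority)
  expect_identical(res2$report$nodes_created, 0L)
  expect_identical(ordered_sig(res2$tree), ordered_sig(res$tree))

  # conservation: every sample's pre-update defining markers still lie on
  # its post-update root path (unless their marker was repositioned away)
  pre <- assign_samples(fx$tree, fx$genotypes, exclude = fx$new_markers)
  post <- res$report$assignments
  moved <- c("M154", "M281")
  for (i in seq_len(nrow(pre))) {
    old_node <- pre$node_id[i]
    old_markers <- setdiff(fx$tree$markers[[old_node]], moved)
    if (!length(old_markers)) next
    new_node <- post$node_id[match(pre$sample[i], post$sample)]
    path_markers <- unlist(res$tree$markers[
      haplotree:::ht_path_to_root(res$tree, new_node)])
    expect_true(all(old_markers %in% path_markers))
  }

  # empty marker list: identity update
  res3 <- update_tree(fx$tree, fx$genotypes, character(), prior = fx$prior)
  expect_length(res3$report$events, 0L)
  expect_identical(ordered_sig(res3$tree), ordered_sig(fx$tree))
})

test_that("update recovers k planted novel branch markers exactly", {
  for (seed in c(2, 4, 6)) {
    cfg <- sim_config(n_leaves = 8, samples_per_node = 2, seed = seed)
    truth <- simulate_tree(cfg)
    sim <- simulate_genotypes(truth, cfg)
    # strip every single-marker leaf-ward node to build a reference tree
    single <- which(lengths(truth$markers) == 1L &
                      seq_along(truth$markers) != 1L)
    strip <- utils::tail(single, 3L)
    ref <- truth
    removed <- character()
    for (v in sort(strip, decreasing = TRUE)) {
      removed <- c(removed, ref$markers[[v]])
      ref <- haplotree:::ht_remove_node(ref, v)
    }
    res <- update_tree(ref, sim$matrix, removed)
    expect_identical(res$report$nodes_created, length(removed))
    expect_true(ht_isomorphic(res$tree, truth))
  }
})

test_that("final topology is invariant to the processing order of new
           markers on laminar data", {
  cfg <- sim_config(n_leaves = 7, samples_per_node = 2, seed = 9)
  truth <- simulate_tree(cfg)
  sim <- simulate_genotypes(truth, cfg)
  single <- which(lengths(truth$markers) == 1L &
                    seq_along(truth$markers) != 1L)
  strip <- utils::tail(single, 4L)
  ref <- truth
  removed <- character()
  for (v in sort(strip, decreasing = TRUE)) {
    removed <- c(removed, ref$markers[[v]])
    ref <- haplotree:::ht_remove_node(ref, v)
  }
  # force different processing orders by single-marker updates
  set.seed(1)
  for (rep in 1:4) {
    perm <- sample(removed)
    tr <- ref
    for (m in perm) {
      off <- setdiff(removed, c(unlist(tr$markers), m))
      tr <- update_tree(tr, sim$matrix, m, exclude_markers = off)$tree
    }
    expect_true(ht_isomorphic(tr, truth))
  }
})
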