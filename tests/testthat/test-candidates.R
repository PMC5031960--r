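sp6 <- species_tree_default()

clean_family <- function(seed = 4, length = 300) {
  fam <- simulate_gene_family(sp6, birth_rate = 0.25, death_rate = 0,
                              seed = seed)
  aln <- evolve_sequences(fam$gene_tree_true, length, seed = seed + 1)
  bt <- bootstrap_supports(aln, n_reps = 40, seed = seed + 2)
  list(fam = fam, aln = aln, tree = bt)
}

test_that("fully supported trees yield candidates differing only by rooting", {
  fx <- clean_family()
  # force all supports to 100: contraction never fires
  g <- fx$tree
  g$support[!is.na(g$support)] <- 100
  cands <- generate_candidates(g, sp6, fx$aln, thresholds = c(20, 50, 90),
                               max_solutions = 4)
  n_edges <- sum(g$parent > 0)
  expect_lte(nrow(cands), n_edges)
  # unrooted topology identical across candidates
  unrooted_keys <- vapply(cands$tree, function(t) {
    paste(sort(unique(genetrace:::split_keys(t))), collapse = ";")
  }, "")
  expect_equal(length(unique(unrooted_keys)), 1)
  # multiplicities account for every threshold x rooting x refinement
  expect_equal(sum(cands$n), 3 * n_edges)
})

test_that("threshold 101 candidates are refinements of the star tree", {
  fx <- clean_family(seed = 8, length = 200)
  cands <- generate_candidates(fx$tree, sp6, fx$aln, thresholds = 101,
                               max_solutions = 4)
  expect_gt(nrow(cands), 0)
  expect_true(all(vapply(cands$tree, genetrace:::is_binary_gtree, TRUE)))
})

test_that("candidate costs never exceed the unrefined tree's cost", {
  fx <- clean_family(seed = 12, length = 200)
  cands <- generate_candidates(fx$tree, sp6, fx$aln,
                               thresholds = c(30, 60, 90), max_solutions = 4)
  # cost of the unrefined binary input under every rooting
  unrefined <- vapply(enumerate_rootings(fx$tree), function(r) {
    lca_reconcile(r, sp6)$cost
  }, 0L)
  expect_true(all(cands$cost <= max(unrefined)))
  expect_lte(min(cands$cost), min(unrefined))
})

test_that("selection keeps SH survivors with minimal cost", {
  fx <- clean_family(seed = 16, length = 250)
  cands <- generate_candidates(fx$tree, sp6, fx$aln,
                               thresholds = c(40, 80), max_solutions = 4)
  best <- select_best(cands, alpha = 0.05, n_rell = 500, seed = 1)
  expect_gt(nrow(best), 0)
  expect_true(all(best$cost == min(best$cost)))
  expect_true(all(best$sh_p[best$loglik == max(cands$loglik)] >= 0.05 |
                    best$loglik == max(cands$loglik)))
  # single candidate: returned as is
  one <- select_best(cands[1, ], seed = 1)
  expect_equal(nrow(one), 1)
})

test_that("the greedy consensus honors majority and unanimity", {
  t1 <- read_gtree("((A.a,B.b),(C.c,D.d));")
  t2 <- read_gtree("((A.a,B.b),(C.c,D.d));")
  t3 <- read_gtree("(((A.a,C.c),B.b),D.d);")
  # identical input trees: the consensus is that tree
  cons_same <- consensus_extended_majority(list(t1, t2))
  expect_equal(topo_key(cons_same), topo_key(t1))
  # 2-vs-1 conflict: the majority resolution wins
  cons <- consensus_extended_majority(list(t1, t2, t3))
  keys <- genetrace:::clade_keys(cons)[genetrace:::gtree_internal(cons)]
  expect_true("A.a|B.b" %in% keys)
  expect_false("A.a|C.c" %in% keys)
  # every clade with frequency > 1/2 is present
  expect_true("C.c|D.d" %in% keys)
  expect_error(consensus_extended_majority(list(t1, read_gtree("(A.a,B.b,X.x);"))),
               class = "genetrace_input_error")
})

test_that("event supports are exact frequencies over replicates", {
  fx <- clean_family(seed = 20, length = 300)
  cands <- generate_candidates(fx$tree, sp6, fx$aln,
                               thresholds = c(30, 70), max_solutions = 4)
  best <- select_best(cands, alpha = 0.05, n_rell = 300, seed = 2)
  fin <- final_tree_and_support(best, cands, alignment = fx$aln,
                                n_boot = 20, seed = 3)
  expect_true(all(fin$node_support$support >= 0))
  expect_true(all(fin$node_support$support <= 1))
  # all replicates identical => every node support 1
  solo <- cands[1, ]
  fin1 <- final_tree_and_support(solo, solo)
  expect_true(all(fin1$node_support$support == 1))
  # a clade absent from half the replicates has support <= 0.5
  two <- cands[1:min(2, nrow(cands)), ]
  if (nrow(two) == 2) {
    two$n <- c(1L, 1L)
    fin2 <- final_tree_and_support(two[1, ], two)
    k1 <- genetrace:::clade_keys(two$tree[[1]])
    k2 <- genetrace:::clade_keys(two$tree[[2]])
    only1 <- setdiff(k1[genetrace:::gtree_internal(two$tree[[1]])],
                     k2[genetrace:::gtree_internal(two$tree[[2]])])
    if (length(only1)) {
      sup <- fin2$node_support$support[fin2$node_support$clade %in% only1]
      expect_true(all(sup <= 0.5))
    }
  }
})

test_that("the family report matches simulator ground truth", {
  # empty input: header only
  empty <- family_report(list())
  expect_equal(nrow(empty), 0)
  # one gene per species, no events
  fam <- simulate_gene_family(sp6, 0, 0, seed = 1)
  rec <- lca_reconcile(fam$gene_tree_true, sp6)
  rep1 <- family_report(list(congruent = rec), species = species_taxa(sp6))
  expect_equal(unname(unlist(rep1[1, species_taxa(sp6)])), rep(1L, 6))
  expect_equal(rep1$dup_count, 0L)
  # simulated families with known counts
  fams <- lapply(1:3, function(s) {
    f <- simulate_gene_family(sp6, 0.35, 0, seed = s + 30)
    lca_reconcile(f$gene_tree_true, sp6)
  })
  truth <- lapply(1:3, function(s) simulate_gene_family(sp6, 0.35, 0, seed = s + 30))
  rep3 <- family_report(fams, species = species_taxa(sp6))
  for (i in 1:3) {
    expect_equal(rep3$dup_count[i], truth[[i]]$true_dup_count)
    expect_equal(rep3$loss_count[i], 0L)
    cnt <- table(truth[[i]]$locus_map$species)
    for (s in names(cnt)) {
      expect_equal(rep3[[s]][i], as.integer(cnt[[s]]))
    }
  }
})
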