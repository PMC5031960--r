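test_that("corrected distances behave at the anchors", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  d0 <- protein_distance_matrix(aln)
  expect_true(all(d0 == 0))
  # 10 differing of 100 ungapped columns: p = 0.10, d = -log(0.9)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  d <- protein_distance_matrix(c(a = s1, b = s2, c = s1))
  expect_equal(d["a", "b"], -log(1 - 0.10))
  # gapped columns are excluded pairwise
  g1 <- "AC-A"
  g2 <- "ACG-"
  dg <- protein_distance_matrix(c(a = g1, b = g2, c = "ACGA"))
  expect_equal(dg["a", "b"], 0)  # only columns 1-2 shared, both identical
})

test_that("saturated pairs are capped with a warning", {
  s1 <- paste(rep("A", 50), collapse = "")
  s2 <- paste(rep("C", 50), collapse = "")
  expect_warning(d <- protein_distance_matrix(c(a = s1, b = s2, c = s1)),
                 "capped")
  expect_equal(d["a", "b"], -log(1 - 0.93))
})

test_that("three-taxon NJ solves the three-point equations", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- neighbor_joining(d)
  lens <- setNames(g$length[gtree_leaves(g)], g$label[gtree_leaves(g)])
  expect_equal(lens[["a"]], (3 + 5 - 6) / 2)
  expect_equal(lens[["b"]], (3 + 6 - 5) / 2)
  expect_equal(lens[["c"]], (5 + 6 - 3) / 2)
})

test_that("NJ recovers additive four-taxon trees", {
  phy <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  d <- ape::cophenetic.phylo(phy)
  g <- neighbor_joining(d)
  expect_equal(phangorn::RF.dist(ape::unroot(phy), gtree_to_phylo(g)), 0)
})

test_that("NJ is consistent on additive matrices (property run)", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n)
    d <- ape::cophenetic.phylo(phy)
    g <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(phy), gtree_to_phylo(g)), 0,
                 info = paste("instance", i))
  }
})

test_that("malformed distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(d), class = "genetrace_input_error")
})

test_that("bootstrap supports hit the degenerate anchors", {
  # constant alignment: every replicate identical, all supports 100
  fam <- simulate_gene_family(birth_rate = 0, death_rate = 0, seed = 1)
  aln <- evolve_sequences(fam$gene_tree_true, 500, seed = 2)
  bt <- bootstrap_supports(aln, n_reps = 20, seed = 3)
  internal <- setdiff(gtree_internal(bt), bt$root)
  # single replicate: supports are 0 or 100
  bt1 <- bootstrap_supports(aln, n_reps = 1, seed = 4)
  sup1 <- na.omit(bt1$support[setdiff(gtree_internal(bt1), bt1$root)])
  expect_true(all(sup1 %in% c(0, 100)))
  # long alignment, well-separated branches: all true bipartitions >= 90
  expect_true(all(na.omit(bt$support[internal]) >= 90))
})

test_that("bootstrap supports are invariant to leaf input order", {
  fam <- simulate_gene_family(birth_rate = 0.3, death_rate = 0, seed = 5)
  aln <- evolve_sequences(fam$gene_tree_true, 300, seed = 6)
  bt1 <- bootstrap_supports(aln, n_reps = 30, seed = 7)
  bt2 <- bootstrap_supports(rev(aln), n_reps = 30, seed = 7)
  s1 <- setNames(bt1$support[setdiff(gtree_internal(bt1), bt1$root)],
                 genetrace:::internal_splits(bt1))
  s2 <- setNames(bt2$support[setdiff(gtree_internal(bt2), bt2$root)],
                 genetrace:::internal_splits(bt2))
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("too-short alignments are input errors", {
  expect_error(bootstrap_supports(c(a = "A", b = "A", c = "A"), seed = 1),
               class = "genetrace_input_error")
})
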