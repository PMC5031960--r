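sp6 <- species_tree_default()

test_that("event-free simulation reproduces the species tree", {
  fam <- simulate_gene_family(sp6, birth_rate = 0, death_rate = 0,
                              root_copies = 1, seed = 1)
  expect_equal(fam$true_dup_count, 0L)
  expect_equal(fam$true_loss_count, 0L)
  key <- gsub("\\.g1", "", topo_key(fam$gene_tree_true))
  expect_equal(key, topo_key(sp6))
})

test_that("two root copies force exactly one duplication at the root", {
  fam <- simulate_gene_family(sp6, 0, 0, root_copies = 2, seed = 1)
  expect_equal(fam$true_dup_count, 1L)
  expect_equal(fam$true_loss_count, 0L)
  expect_equal(fam$gene_tree_true$event[fam$gene_tree_true$root], "duplication")
  expect_equal(nrow(fam$locus_map), 12)
})

test_that("death rate zero forbids losses and keeps all taxa", {
  fam <- simulate_gene_family(sp6, birth_rate = 0.3, death_rate = 0, seed = 7)
  expect_equal(fam$true_loss_count, 0L)
  expect_gte(nrow(fam$locus_map), length(species_taxa(sp6)))
  # replaying the event log reproduces the truth exactly
  rp <- replay_family_events(fam$events)
  expect_equal(rp$dup_count, fam$true_dup_count)
  expect_equal(rp$loss_count, fam$true_loss_count)
})

test_that("event-log replay matches the pruned tree under losses too", {
  for (s in 1:10) {
    fam <- simulate_gene_family(sp6, birth_rate = 0.5, death_rate = 0.3, seed = s)
    rp <- replay_family_events(fam$events)
    expect_equal(rp$dup_count, fam$true_dup_count)
    expect_equal(rp$loss_count, fam$true_loss_count)
    if (!fam$empty) {
      expect_equal(sum(fam$gene_tree_true$event == "duplication", na.rm = TRUE),
                   fam$true_dup_count)
    }
  }
})

test_that("an all-extinct family is an explicit empty result", {
  fam <- simulate_gene_family(sp6, birth_rate = 0, death_rate = 50, seed = 2)
  expect_true(fam$empty)
  expect_null(fam$gene_tree_true)
  expect_gt(fam$true_loss_count, 0)
})

test_that("simulation is deterministic and bit-identical on disk", {
  f1 <- simulate_gene_family(sp6, 0.3, 0.1, seed = 11)
  f2 <- simulate_gene_family(sp6, 0.3, 0.1, seed = 11)
  expect_identical(f1$events, f2$events)
  s1 <- evolve_sequences(f1$gene_tree_true, 100, seed = 5)
  s2 <- evolve_sequences(f2$gene_tree_true, 100, seed = 5)
  expect_identical(s1, s2)
  p1 <- file.path(tempdir(), "a.fasta"); p2 <- file.path(tempdir(), "b.fasta")
  write_fasta(s1, p1); write_fasta(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(gtree_newick(f1$gene_tree_true, nhx = TRUE),
                   gtree_newick(f2$gene_tree_true, nhx = TRUE))
})

test_that("zero-length branches copy sequences unchanged", {
  tr <- read_gtree("((A.a:0,B.b:0):0,C.c:0);")
  seqs <- evolve_sequences(tr, 80, seed = 3)
  expect_equal(seqs[["A.a"]], seqs[["B.b"]])
  expect_equal(seqs[["A.a"]], seqs[["C.c"]])
})

test_that("sequence divergence matches the model expectation", {
  tr <- read_gtree("(A.a:0,B.b:0.5);")
  n <- 200
  seqs <- evolve_sequences(tr, n, seed = 9)
  p_obs <- mean(strsplit(seqs[[1]], "")[[1]] != strsplit(seqs[[2]], "")[[1]])
  p_exp <- genetrace:::expected_pdist(genetrace:::aa_model("LG"), 0.5)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("unknown substitution model raises a configuration error", {
  tr <- read_gtree("(A.a:0.1,B.b:0.1);")
  expect_error(evolve_sequences(tr, 10, subs_model = "WAG9", seed = 1),
               class = "genetrace_config_error")
  expect_error(evolve_sequences(tr, 10, subs_model = "WAG9", seed = 1),
               "supported models")
})

test_that("genome simulation preserves gene content and distance bounds", {
  anc <- random_genome(30, 2, seed = 5, name = "anc")
  sg0 <- simulate_genome_evolution(anc, sp6, ops_per_branch = 0, seed = 1)
  for (g in sg0$leaves) expect_true(genetrace:::genome_equal(g, anc))
  sg <- simulate_genome_evolution(anc, sp6, ops_per_branch = 3, seed = 2)
  for (g in sg$leaves) {
    expect_identical(genome_genes(g), genome_genes(anc))
  }
  # rha is 4 branches from the root: at most 12 operations
  expect_lte(dcj_distance(anc, sg$leaves$rha), 12)
  sg2 <- simulate_genome_evolution(anc, sp6, ops_per_branch = 3, seed = 2)
  expect_identical(lapply(sg$leaves, genetrace:::genome_partner,
                          genome_genes(anc)),
                   lapply(sg2$leaves, genetrace:::genome_partner,
                          genome_genes(anc)))
})

test_that("GRIMM output is bit-identical for a fixed seed", {
  anc <- random_genome(12, 2, circular = c(FALSE, TRUE), seed = 8, name = "anc")
  p1 <- file.path(tempdir(), "g1.grimm"); p2 <- file.path(tempdir(), "g2.grimm")
  write_grimm(simulate_genome_evolution(anc, sp6, 2, seed = 3)$leaves, p1)
  write_grimm(simulate_genome_evolution(anc, sp6, 2, seed = 3)$leaves, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_grimm(p1)
  expect_named(back, names(simulate_genome_evolution(anc, sp6, 2, seed = 3)$leaves))
})
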