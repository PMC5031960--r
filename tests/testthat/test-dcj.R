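test_that("adjacency graph anchors hold", {
  a <- genome("a", list(c(1, 2, 3)))
  self <- build_adjacency_graph(a, a)
  expect_equal(self$C + self$I / 2, self$N)
  expect_equal(self$d, 0L)
  # single inversion
  b <- genome("b", list(c(1, -2, 3)))
  expect_equal(dcj_distance(a, b), 1L)
  # rotation of a linear chromosome needs two operations
  c3 <- genome("c", list(c(2, 3, 1)))
  expect_equal(dcj_distance(a, c3), 2L)
})

test_that("gene content mismatches list the symmetric difference", {
  a <- genome("a", list(c(1, 2, 3)))
  b <- genome("b", list(c(1, 2, 4)))
  expect_error(dcj_distance(a, b), "3", class = "genetrace_input_error")
  expect_error(dcj_distance(a, b), "4", class = "genetrace_input_error")
})

test_that("distance equals BFS shortest path on random small genomes", {
  for (i in 1:40) {
    a <- random_test_genome(sample(2:5, 1), seed = i, name = "a")
    b <- random_test_genome(length(genome_genes(a)), seed = 5000 + i, name = "b")
    expect_equal(dcj_distance(a, b), oracle_dcj_bfs(a, b),
                 info = paste("pair", i))
  }
})

test_that("DCJ distance is a metric", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    a <- random_test_genome(n, seed = i * 3 + 1, name = "a")
    b <- random_test_genome(n, seed = i * 3 + 2, name = "b")
    c3 <- random_test_genome(n, seed = i * 3 + 3, name = "c")
    dab <- dcj_distance(a, b)
    expect_equal(dab, dcj_distance(b, a))
    expect_equal(dcj_distance(a, a), 0L)
    expect_lte(dcj_distance(a, c3), dab + dcj_distance(b, c3))
  }
})

test_that("short random walks on large genomes rarely cancel", {
  # 3 random operations on a 30-gene genome give distance exactly 3 in
  # the vast majority of replicates (measured 98/100 at these seeds)
  eq <- 0L
  for (s in 1:100) {
    anc <- random_genome(30, 2, seed = s, name = "anc")
    u <- genome_genes(anc)
    p <- genetrace:::genome_partner(anc, u)
    withr::with_seed(50000 + s, {
      for (k in 1:3) {
        ops <- genetrace:::all_dcj_ops(p)
        p <- genetrace:::apply_op(p, ops[[sample.int(length(ops), 1)]])
      }
    })
    moved <- genetrace:::partner_genome(p, u, name = "m")
    eq <- eq + (dcj_distance(anc, moved) == 3L)
  }
  expect_gte(eq, 90)
})

test_that("k random operations move at most k away", {
  sp <- species_tree_default()
  for (s in 1:20) {
    anc <- random_genome(20, 2, seed = s, name = "anc")
    sg <- simulate_genome_evolution(anc, sp, ops_per_branch = 3, seed = s + 100)
    # the branch to 'the' applies exactly 3 operations from the ancestor
    expect_lte(dcj_distance(anc, sg$leaves$the), 3)
  }
})

test_that("sorting scenarios are optimal and transform source into target", {
  for (i in 1:30) {
    n <- sample(3:30, 1)
    a <- random_test_genome(n, seed = i * 7 + 1, name = "a")
    b <- random_test_genome(n, seed = i * 7 + 2, name = "b")
    sc <- dcj_sort(a, b)
    d <- dcj_distance(a, b)
    expect_equal(nrow(sc$ops), d, info = paste("pair", i))
    expect_true(genetrace:::genome_equal(apply_dcj(a, sc), b))
    # every prefix strictly decreases the distance to the target
    if (d > 0 && i <= 10) {
      for (k in seq_len(d)) {
        expect_equal(dcj_distance(apply_dcj(a, sc, k), b), d - k)
      }
    }
  }
  # identical genomes: empty scenario
  g <- random_test_genome(5, seed = 1)
  expect_equal(nrow(dcj_sort(g, g)$ops), 0)
})

test_that("median degenerate anchors hold", {
  a <- genome("a", list(c(1, 2, 3, 4)))
  c3 <- genome("c", list(c(-3, 1, 2, 4)))
  m1 <- dcj_median(a, a, c3, mode = "exact")
  expect_equal(m1$score, dcj_distance(a, c3))
  m2 <- dcj_median(a, a, a, mode = "exact")
  expect_equal(m2$score, 0L)
  expect_true(genetrace:::genome_equal(m2$median, a))
})

test_that("exact median matches exhaustive enumeration", {
  for (i in 1:5) {
    a <- random_test_genome(4, seed = i * 11 + 1, name = "a")
    b <- random_test_genome(4, seed = i * 11 + 2, name = "b")
    c3 <- random_test_genome(4, seed = i * 11 + 3, name = "c")
    m <- dcj_median(a, b, c3, mode = "exact")
    expect_equal(m$score, oracle_median_score(a, b, c3),
                 info = paste("triple", i))
    expect_gte(m$score, m$lower_bound)
  }
})

test_that("exact median above the size cap is a capability error", {
  a <- random_test_genome(8, seed = 1, name = "a")
  b <- random_test_genome(8, seed = 2, name = "b")
  c3 <- random_test_genome(8, seed = 3, name = "c")
  expect_error(dcj_median(a, b, c3, mode = "exact"),
               class = "genetrace_capability_error")
  m <- dcj_median(a, b, c3, mode = "heuristic")
  expect_gte(m$score, m$lower_bound)
})

test_that("ancestor inference recovers simulated ancestors", {
  recovered <- 0L
  for (s in 1:10) {
    anc <- random_genome(30, 1, seed = s, name = "anc")
    p_anc <- genetrace:::genome_partner(anc, genome_genes(anc))
    leaves <- lapply(1:3, function(i) {
      p <- p_anc
      withr::with_seed(s * 10 + i, {
        for (k in 1:2) {
          ops <- genetrace:::all_dcj_ops(p)
          p <- genetrace:::apply_op(p, ops[[sample.int(length(ops), 1)]])
        }
      })
      genetrace:::partner_genome(p, genome_genes(anc), name = paste0("leaf", i))
    })
    names(leaves) <- paste0("leaf", 1:3)
    inf <- infer_ancestor(leaves, mode = "heuristic")
    expect_lte(sum(inf$branch_counts$operations), 6)
    if (dcj_distance(inf$ancestor, anc) == 0) recovered <- recovered + 1L
  }
  expect_gte(recovered, 6)  # majority of runs recover the true ancestor
})
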