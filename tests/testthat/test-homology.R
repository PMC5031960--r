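test_that("self-alignment is perfect", {
  h <- local_align("MKV", "MKV")
  expect_equal(h$percent_identity, 100)
  expect_equal(h$query_coverage, 1.0)
  expect_equal(h$trimmed_subject, "MKV")
})

test_that("the classic textbook local alignment is reproduced", {
  # HEAGAWGHEE vs PAWHEAE, BLOSUM50, linear gap penalty 8: AWGHE/AW-HE, 28
  h <- local_align("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                   gap_open = 0, gap_extend = 8)
  expect_equal(h$score, 28)
  expect_equal(h$aligned_query, "AWGHE")
  expect_equal(h$aligned_subject, "AW-HE")
})

test_that("unrelated sequences yield at most a single-residue match", {
  h <- local_align("MKVL", "AAAA")
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  best_single <- max(e$BLOSUM62[c("M", "K", "V", "L"), "A"])
  expect_lte(h$score, max(best_single, 0))
})

test_that("alignment scores match an independent dynamic program", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  set.seed(42)
  aas <- genetrace:::.aa_alphabet
  for (i in 1:25) {
    a <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    h <- local_align(a, b, gap_open = 11, gap_extend = 1)
    expect_equal(h$score, oracle_sw_score(a, b, m, 11, 1),
                 info = paste(a, b))
  }
})

test_that("empty sequences are input errors", {
  expect_error(local_align("", "MKV"), class = "genetrace_input_error")
})

planted_fixture <- function() {
  fam <- simulate_gene_family(birth_rate = 0.25, death_rate = 0, seed = 3)
  seqs <- evolve_sequences(fam$gene_tree_true, 200, seed = 11)
  query <- seqs[[1]]
  decoys <- withr::with_seed(99, setNames(
    vapply(1:50, function(i) {
      paste(sample(strsplit(query, "")[[1]]), collapse = "")
    }, ""),
    sprintf("decoy%02d", 1:50)
  ))
  list(query = query, planted = seqs, db = c(seqs, decoys))
}

test_that("the screen keeps exactly the planted homologs at 35%/50%", {
  fx <- planted_fixture()
  hits <- screen_homologs(fx$query, fx$db)
  expect_setequal(hits$subject_id, names(fx$planted))
  # verify directly that every decoy fails a threshold
  all_hits <- screen_homologs(fx$query, fx$db, keep_all = TRUE)
  decoy_rows <- all_hits[grepl("^decoy", all_hits$subject_id), ]
  expect_true(all(decoy_rows$percent_identity < 35 |
                    decoy_rows$query_coverage < 0.5))
})

test_that("screen edge cases behave", {
  fx <- planted_fixture()
  # the query itself comes back at identity 100
  hits <- screen_homologs(fx$query, c(self = fx$query))
  expect_equal(hits$percent_identity, 100)
  # unsatisfiable threshold
  expect_equal(nrow(screen_homologs(fx$query, fx$db, min_identity = 101)), 0)
  # empty database is not an error
  expect_equal(nrow(screen_homologs(fx$query, character(0))), 0)
})

test_that("filtering is monotone in both thresholds", {
  fx <- planted_fixture()
  base <- screen_homologs(fx$query, fx$db, min_identity = 30, min_coverage = 0.4)
  for (mi in c(40, 60, 80)) {
    tighter <- screen_homologs(fx$query, fx$db, min_identity = mi,
                               min_coverage = 0.4)
    expect_true(all(tighter$subject_id %in% base$subject_id))
  }
  for (mc in c(0.6, 0.9)) {
    tighter <- screen_homologs(fx$query, fx$db, min_identity = 30,
                               min_coverage = mc)
    expect_true(all(tighter$subject_id %in% base$subject_id))
  }
})

test_that("screening a larger database never loses kept hits", {
  fx <- planted_fixture()
  small <- screen_homologs(fx$query, fx$planted)
  big <- screen_homologs(fx$query, fx$db)
  expect_true(all(small$subject_id %in% big$subject_id))
})

test_that("isoform dedup keeps the best hit per locus", {
  hits <- tibble::tibble(
    query_id = "q",
    subject_id = c("g1.i1", "g1.i2", "g2.i1", "g3.i1", "g3.i2", "g4.i1"),
    percent_identity = 90, query_coverage = 1,
    score = c(50, 40, 30, 25, 25, 20),
    trimmed_subject = c("AAAA", "AAA", "AA", "AAA", "AAAA", "A")
  )
  locus_map <- tibble::tibble(
    gene_id = c("g1.i1", "g1.i2", "g2.i1", "g3.i1", "g3.i2"),
    locus_id = c("L1", "L1", "L2", "L3", "L3")
  )
  expect_warning(out <- dedup_isoforms(hits, locus_map), "singleton")
  # 3 loci + 1 singleton
  expect_equal(nrow(out), 4)
  expect_true("g1.i1" %in% out$subject_id)   # higher score wins
  expect_false("g1.i2" %in% out$subject_id)
  expect_true("g3.i2" %in% out$subject_id)   # tie: longer trimmed wins
  expect_true("g4.i1" %in% out$subject_id)   # singleton kept
  # all-distinct loci: output equals input
  solo <- hits[c(1, 3, 6), ]
  lm2 <- tibble::tibble(gene_id = solo$subject_id, locus_id = c("a", "b", "c"))
  expect_equal(dedup_isoforms(solo, lm2)$subject_id, solo$subject_id)
})
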