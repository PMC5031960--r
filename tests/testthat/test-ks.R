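test_that("NG86 hand-checked anchors hold", {
  # two glycine codons, one synonymous third-position difference:
  # S = 2, pS = 1/2, Ks = -(3/4) ln(1/3)
  k <- ks_ng86("GGGGGA", "GGGGGG")
  expect_equal(k$s_sites, 2)
  expect_equal(k$sd, 1)
  expect_equal(k$ps, 0.5)
  expect_equal(k$ks, -0.75 * log(1 / 3), tolerance = 1e-6)
  expect_false(k$ks_saturated)
  # identical sequences
  k0 <- ks_ng86("ATGGCT", "ATGGCT")
  expect_equal(k0$ks, 0)
  expect_equal(k0$ka, 0)
})

test_that("saturation flags undefined Ks", {
  # four glycine codons differing at every synonymous site: pS = 1
  k <- ks_ng86("GGAGGAGGAGGA", "GGGGGCGGTGGG")
  expect_gte(k$ps, 0.75)
  expect_true(k$ks_saturated)
  expect_true(is.na(k$ks))
})

test_that("site counts are conserved: S + N = sequence length", {
  set.seed(4)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    names(which(Biostrings::GENETIC_CODE == "*")))
  for (i in 1:20) {
    n <- sample(2:10, 1)
    a <- paste(sample(codons, n, replace = TRUE), collapse = "")
    b <- paste(sample(codons, n, replace = TRUE), collapse = "")
    k <- ks_ng86(a, b)
    expect_equal(k$s_sites + k$n_sites, nchar(a))
  }
})

test_that("malformed coding sequences are input errors", {
  expect_error(ks_ng86("ATG", "ATGGCT"), class = "genetrace_input_error")
  expect_error(ks_ng86("ATGG", "ATGG"), class = "genetrace_input_error")
  expect_error(ks_ng86("TAAGCT", "TAAGCT"), "stop",
               class = "genetrace_input_error")
})

synthetic_pairs <- function() {
  # recent pairs around Ks 0.2, ancient around 1.8
  withr::with_seed(8, tibble::tibble(
    gene_a = sprintf("a%03d", 1:200),
    gene_b = sprintf("b%03d", 1:200),
    ks = c(rgamma(100, shape = 16, rate = 80),    # mean 0.2
           rgamma(100, shape = 16, rate = 8.9)),  # mean 1.8
    similarity = c(rnorm(100, 85, 3), rnorm(100, 55, 3)),
    truth = rep(c("ortholog", "out_paralog"), each = 100)
  ))
}

test_that("a mixture of recent and ancient pairs separates cleanly", {
  pairs <- synthetic_pairs()
  out <- classify_pairs(pairs, ks_cut = 1.0, sim_cut = 70)
  expect_equal(sum(out$classification != out$truth), 0)
})

test_that("classification is monotone in the Ks threshold", {
  pairs <- synthetic_pairs()
  prev <- character(0)
  for (cut in c(0.3, 0.6, 1.0, 2.0, Inf)) {
    out <- classify_pairs(pairs, ks_cut = cut, sim_cut = 0)
    now <- out$gene_a[out$classification == "ortholog"]
    expect_true(all(prev %in% now))
    prev <- now
  }
  # unbounded thresholds call every defined-Ks pair an ortholog
  all_in <- classify_pairs(pairs, ks_cut = Inf, sim_cut = 0)
  expect_true(all(all_in$classification == "ortholog"))
  # saturated pairs are out-paralogs
  pairs$ks[1] <- NA
  out <- classify_pairs(pairs, ks_cut = Inf, sim_cut = 0)
  expect_equal(out$classification[1], "out_paralog")
  # no thresholds: unassigned
  expect_true(all(classify_pairs(pairs)$classification == "unassigned"))
})

test_that("the fitted Ks split lands between the two components", {
  pairs <- synthetic_pairs()
  cut <- ks_threshold_split(pairs$ks)
  expect_gt(cut, max(pairs$ks[pairs$truth == "ortholog"]) * 0.5)
  expect_lt(cut, 1.8)
  out <- classify_pairs(pairs, ks_cut = cut, sim_cut = 0)
  expect_lte(sum(out$classification != out$truth), 2)
})
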