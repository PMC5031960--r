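# Nei-Gojobori (1986) pathway counting of synonymous and nonsynonymous
# sites/differences with Jukes-Cantor correction.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.nucs <- c("A", "C", "G", "T")

# Synonymous site count of one codon: at each position, the fraction of
# the three possible point changes that preserve the amino acid. Changes
# creating a stop codon count as nonsynonymous, so S + N = 3 per codon.
codon_syn_sites <- function(codon, table) {
  aa <- table[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(.nucs, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (!is.na(table[[alt]]) && table[[alt]] != "*" && table[[alt]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over
# all mutational pathways (all orders of the differing positions).
codon_diffs <- function(ca, cb, table) {
  diff_pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diff_pos) else {
    if (k == 2) list(diff_pos, rev(diff_pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) diff_pos[i])
    }
  }
  sd <- 0; nd <- 0
  for (path in perms) {
    cur <- ca
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      syn <- table[[cur]] != "*" && table[[nxt]] != "*" &&
        table[[cur]] == table[[nxt]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
  }
  c(sd = sd / length(perms), nd = nd / length(perms))
}

#' Nei-Gojobori Ks and Ka between two coding sequences
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all mutational pathways per
#' codon), then applies the Jukes-Cantor correction
#' `K = -(3/4) log(1 - (4/3) p)`. Proportions of 3/4 or more are
#' saturated: the corrected rate is undefined and flagged.
#'
#' @param cds_a,cds_b coding sequences (same length, multiple of 3, no
#'   internal stop codons).
#' @return A one-row tibble: `ks`, `ka` (NA when saturated), `ps`, `pn`,
#'   `s_sites`, `n_sites`, `sd`, `nd`, `ks_saturated`, `ka_saturated`.
#' @examples
#' ks_ng86("GGGGGA", "GGGGGG")$ks  # 2 synonymous sites, 1 difference
#' @export
ks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(gsub("U", "T", cds_a)); cds_b <- toupper(gsub("U", "T", cds_b))
  if (nchar(cds_a) != nchar(cds_b)) stop_input("sequences must have equal length")
  if (nchar(cds_a) %% 3 != 0) stop_input("sequence length must be a multiple of 3")
  if (nchar(cds_a) == 0) stop_input("sequences must be nonempty")
  table <- .codon_table()
  n_codons <- nchar(cds_a) / 3
  split_codons <- function(x) {
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  bad <- !ca %in% names(table) | !cb %in% names(table)
  if (any(bad)) stop_input("non-standard codon at position ", which(bad)[1])
  stops <- table[ca] == "*" | table[cb] == "*"
  if (any(stops[-n_codons])) {
    stop_input("internal stop codon at codon ", which(stops)[1])
  }
  # a shared terminal stop is not informative: drop it
  if (stops[n_codons]) {
    ca <- ca[-n_codons]; cb <- cb[-n_codons]
  }
  s_sites <- (sum(vapply(ca, codon_syn_sites, 0, table = table)) +
                sum(vapply(cb, codon_syn_sites, 0, table = table))) / 2
  total_sites <- 3 * length(ca)
  n_sites <- total_sites - s_sites
  d <- rowSums(vapply(seq_along(ca), function(i) codon_diffs(ca[i], cb[i], table),
                      c(sd = 0, nd = 0)))
  ps <- if (s_sites > 0) d[["sd"]] / s_sites else 0
  pn <- if (n_sites > 0) d[["nd"]] / n_sites else 0
  jc <- function(p) {
    if (p >= 0.75) return(c(NA_real_, TRUE))
    c(-0.75 * log(1 - 4 * p / 3), FALSE)
  }
  ks_fit <- jc(ps)
  ka_fit <- jc(pn)
  tibble::tibble(
    ks = ks_fit[1], ka = ka_fit[1], ps = ps, pn = pn,
    s_sites = s_sites, n_sites = n_sites, sd = d[["sd"]], nd = d[["nd"]],
    ks_saturated = as.logical(ks_fit[2]), ka_saturated = as.logical(ka_fit[2])
  )
}

#' Classify duplicate gene pairs as orthologs or out-paralogs
#'
#' Recent pairs born at speciation (orthologs) are separated from older,
#' more divergent pairs descending from an ancient polyploidy
#' (out-paralogs) by joint Ks and similarity thresholds: a pair is an
#' ortholog when `ks <= ks_cut` and `similarity >= sim_cut`. Pairs with
#' saturated (undefined) Ks are out-paralogs; when either threshold is
#' `NULL` the pairs are left `unassigned`.
#'
#' @param pairs a data frame with columns `ks` and `similarity`
#'   (`NA` Ks = saturated).
#' @param ks_cut Ks threshold (synonymous substitutions per synonymous
#'   site), or `NULL`.
#' @param sim_cut similarity threshold (percent), or `NULL`.
#' @return `pairs` as a tibble with a `classification` column.
#' @export
classify_pairs <- function(pairs, ks_cut = NULL, sim_cut = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (is.null(ks_cut) || is.null(sim_cut)) {
    pairs$classification <- "unassigned"
    return(pairs)
  }
  pairs$classification <- ifelse(
    !is.na(pairs$ks) & pairs$ks <= ks_cut & pairs$similarity >= sim_cut,
    "ortholog", "out_paralog"
  )
  pairs
}

#' Fit a Ks threshold by a two-component split
#'
#' Splits a Ks distribution into a recent and an ancient component by
#' one-dimensional 2-means with deterministic quantile initialization and
#' returns the midpoint between the two cluster centers. Useful for
#' setting `ks_cut` when no external threshold is available.
#'
#' @param ks numeric vector of Ks values (NAs dropped).
#' @return The fitted threshold (numeric scalar).
#' @export
ks_threshold_split <- function(ks) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < 4) stop_input("need at least 4 finite Ks values to fit a split")
  centers <- stats::quantile(ks, c(0.25, 0.75), names = FALSE)
  if (diff(centers) < 1e-8) return(mean(centers))
  km <- stats::kmeans(ks, centers = matrix(centers, ncol = 1))
  mean(range(km$centers))
}
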