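# Felsenstein pruning likelihood under an empirical amino-acid model
# with discrete-Gamma rate heterogeneity, and the Shimodaira-Hasegawa
# test via RELL resampling for filtering candidate trees.

#' Per-site log-likelihood of a gene tree
#'
#' Computes the phylogenetic likelihood of an alignment on a tree by the
#' pruning algorithm under a reversible empirical amino-acid model
#' (default Le-Gascuel) with discrete-Gamma(`gamma_categories`) rate
#' heterogeneity. Under a reversible model the likelihood does not
#' depend on the root position, so rooted and unrooted trees give the
#' same total. Gap and `X` characters are treated as missing data.
#'
#' @param tree a `gtree` with branch lengths (substitutions/site).
#' @param alignment named character vector or `AAStringSet`; every leaf
#'   label of `tree` must be present.
#' @param subs_model `"LG"` or `"Poisson"`.
#' @param gamma_categories number of discrete-Gamma categories (1 =
#'   rate homogeneity).
#' @param gamma_alpha Gamma shape; either a number or `"grid"` to pick
#'   the best of a coarse grid (0.25, 0.5, 1, 2, 4) by total
#'   log-likelihood.
#' @return An object of class `site_likelihoods`: list with `site`
#'   (per-site log-likelihood vector), `total`, `alpha`.
#' @export
felsenstein_loglik <- function(tree, alignment, subs_model = "LG",
                               gamma_categories = 4L, gamma_alpha = 1) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  leaves <- gtree_leaves(tree)
  missing <- setdiff(tree$label[leaves], names(alignment))
  if (length(missing)) {
    stop_input("leaf without sequence: ", paste(missing, collapse = ", "))
  }
  if (identical(gamma_alpha, "grid")) {
    grid <- c(0.25, 0.5, 1, 2, 4)
    fits <- lapply(grid, function(a) {
      felsenstein_loglik(tree, alignment, subs_model, gamma_categories, a)
    })
    return(fits[[which.max(vapply(fits, `[[`, 0, "total"))]])
  }
  mod <- aa_model(subs_model)
  S <- unique(nchar(alignment[tree$label[leaves]]))
  if (length(S) != 1) stop_input("aligned sequences must have equal length")
  rates <- if (gamma_categories > 1) {
    discrete_gamma_rates(gamma_alpha, gamma_categories)
  } else 1
  # leaf state indicators, 20 x S each; missing characters = all ones
  leaf_lik <- lapply(leaves, function(v) {
    chars <- strsplit(alignment[[tree$label[v]]], "")[[1]]
    idx <- match(chars, .aa_alphabet)
    L <- matrix(0, 20L, S)
    known <- !is.na(idx)
    L[cbind(idx[known], which(known))] <- 1
    L[, !known] <- 1
    L
  })
  names(leaf_lik) <- as.character(leaves)
  ord <- gtree_postorder(tree)
  per_cat <- matrix(0, length(rates), S)  # log site likelihood per category
  for (ci in seq_along(rates)) {
    r <- rates[ci]
    lik <- vector("list", gtree_n(tree))
    logscale <- rep(0, S)
    for (v in ord) {
      ch <- tree$children[[v]]
      if (length(ch) == 0) {
        lik[[v]] <- leaf_lik[[as.character(v)]]
        next
      }
      L <- matrix(1, 20L, S)
      for (c in ch) {
        t <- tree$length[c]
        if (is.na(t)) t <- 0
        P <- aa_pmatrix(mod, t * r)
        L <- L * (P %*% lik[[c]])
      }
      sc <- apply(L, 2, max)
      sc[sc == 0] <- 1
      lik[[v]] <- sweep(L, 2, sc, "/")
      logscale <- logscale + log(sc)
    }
    per_cat[ci, ] <- log(colSums(mod$pi * lik[[tree$root]])) + logscale
  }
  # average site likelihood over categories in a numerically safe way
  mx <- apply(per_cat, 2, max)
  site <- mx + log(colMeans(exp(sweep(per_cat, 2, mx, "-"))))
  structure(list(site = site, total = sum(site), alpha = gamma_alpha,
                 model = subs_model),
            class = "site_likelihoods")
}

#' @export
print.site_likelihoods <- function(x, ...) {
  cat(sprintf("<site_likelihoods: %d sites, total logL = %.4f>\n",
              length(x$site), x$total))
  invisible(x)
}

#' Shimodaira-Hasegawa filter over candidate trees
#'
#' Tests every candidate tree against the maximum-likelihood candidate
#' with the SH test using RELL (resampling estimated log-likelihoods)
#' with centering, and returns the indices of candidates that are not
#' rejected at level `alpha`. The best tree is always retained.
#'
#' @param candidates a list of `site_likelihoods` (or numeric per-site
#'   log-likelihood vectors), all of the same length, or a matrix with
#'   one row per candidate.
#' @param n_rell number of RELL replicates (default 1000).
#' @param seed integer seed.
#' @param alpha significance level; `alpha = 0` retains everything.
#' @return Integer vector of retained candidate indices, with the SH
#'   p-values as the `p_values` attribute.
#' @export
sh_filter <- function(candidates, n_rell = 1000L, seed, alpha = 0.05) {
  L <- if (is.matrix(candidates)) candidates else {
    do.call(rbind, lapply(candidates, function(x) {
      if (inherits(x, "site_likelihoods")) x$site else as.numeric(x)
    }))
  }
  m <- nrow(L); S <- ncol(L)
  if (m == 1) {
    return(structure(1L, p_values = 1))
  }
  totals <- rowSums(L)
  delta <- max(totals) - totals
  # candidates tied with the best up to floating-point noise (e.g. two
  # rootings of one unrooted topology under a reversible model) are
  # never rejected: their RELL comparisons would be coin flips
  tie_tol <- 1e-8 * max(1, abs(max(totals)))
  p <- with_seed(seed, {
    counts <- stats::rmultinom(n_rell, S, rep(1 / S, S))  # S x B
    R <- L %*% counts                                     # m x B
    Rc <- R - rowMeans(R)
    Smax <- apply(Rc, 2, max)
    vapply(seq_len(m), function(i) mean(Smax - Rc[i, ] > delta[i]), 0)
  })
  p[delta <= tie_tol] <- 1
  keep <- which(p >= alpha | delta <= tie_tol)
  keep <- sort(union(keep, which.max(totals)))
  structure(keep, p_values = p)
}
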