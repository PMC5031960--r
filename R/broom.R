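#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reconciliation into a per-node tibble
#'
#' @param x a `reconciliation` from [lca_reconcile()].
#' @param ... unused.
#' @return A tibble with one row per gene-tree node: `node`, `label`,
#'   `is_leaf`, `species` (image in the species tree), `event`,
#'   `branch_length`, `support`.
#' @exportS3Method generics::tidy
tidy.reconciliation <- function(x, ...) {
  g <- x$gene_tree
  n <- gtree_n(g)
  tibble::tibble(
    node = seq_len(n),
    label = g$label,
    is_leaf = lengths(g$children) == 0,
    species = vapply(x$mapping, function(s) sp_node_name(x$species_tree, s), ""),
    event = g$event,
    branch_length = g$length,
    support = g$support
  )
}

#' One-row summary of a reconciliation
#'
#' @inheritParams tidy.reconciliation
#' @return A tibble with `n_leaves`, `dup_count`, `loss_count`, `cost`.
#' @exportS3Method generics::glance
glance.reconciliation <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(gtree_leaves(x$gene_tree)),
    dup_count = x$dup_count,
    loss_count = x$loss_count,
    cost = x$cost
  )
}

#' One-row summary of per-site likelihoods
#'
#' @param x a `site_likelihoods` from [felsenstein_loglik()].
#' @param ... unused.
#' @return A tibble with `n_sites`, `total`, `mean_site`, `alpha`,
#'   `model`.
#' @exportS3Method generics::glance
glance.site_likelihoods <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site),
    total = x$total,
    mean_site = mean(x$site),
    alpha = if (is.numeric(x$alpha)) x$alpha else NA_real_,
    model = x$model
  )
}

#' Tidy a simulated family into its locus map with truth columns
#'
#' @param x a `simulated_family`.
#' @param ... unused.
#' @return The locus-map tibble with `true_dup_count` and
#'   `true_loss_count` attached as columns.
#' @exportS3Method generics::tidy
tidy.simulated_family <- function(x, ...) {
  out <- x$locus_map
  out$true_dup_count <- x$true_dup_count
  out$true_loss_count <- x$true_loss_count
  out
}
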