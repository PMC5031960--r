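# Plots mirroring the figures practitioners draw from these analyses:
# per-species homolog-count histograms, Ks distributions with the
# ortholog/out-paralog cut, and event-annotated reconciled trees.

#' Homolog-count histograms per species
#'
#' Bar chart of gene counts per species, faceted by family — the
#' standard companion to a reconciled multi-family analysis.
#'
#' @param report the tibble from [family_report()].
#' @return A ggplot object.
#' @export
plot_family_report <- function(report) {
  count_cols <- setdiff(names(report), c("family", "dup_count", "loss_count"))
  long <- tidyr::pivot_longer(report, dplyr::all_of(count_cols),
                              names_to = "species", values_to = "n_genes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = NULL, y = "homologs") +
    ggplot2::theme_minimal()
}

#' Ks distribution with classification threshold
#'
#' @param pairs a tibble with a `ks` column (e.g. from [classify_pairs()]).
#' @param ks_cut optional threshold drawn as a vertical line.
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(pairs, ks_cut = NULL, bins = 40) {
  p <- ggplot2::ggplot(pairs[is.finite(pairs$ks), ], ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "Ks (synonymous substitutions/site)", y = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(ks_cut)) {
    p <- p + ggplot2::geom_vline(xintercept = ks_cut, linetype = 2, colour = "red")
  }
  p
}

#' Plot a reconciled gene tree with event symbols
#'
#' Draws the gene tree (via ape) with red squares at duplications, green
#' circles at speciations and grey symbols at grafted loss leaves.
#'
#' @param x a `reconciliation` or an event-annotated `gtree`.
#' @param show_support draw event supports (when present) below nodes?
#' @param ... passed to [ape::plot.phylo()].
#' @return Invisibly, the plotted `phylo` object.
#' @export
plot_reconciliation <- function(x, show_support = TRUE, ...) {
  g <- if (inherits(x, "reconciliation")) x$gene_tree else x
  phy <- gtree_to_phylo(g)
  leaves <- gtree_leaves(g)
  internal <- c(g$root, setdiff(gtree_internal(g), g$root))
  ape::plot.phylo(phy, ...)
  ev <- g$event[internal]
  nodes <- length(leaves) + seq_along(internal)
  dup <- !is.na(ev) & ev == "duplication"
  spc <- !is.na(ev) & ev == "speciation"
  if (any(dup)) ape::nodelabels(node = nodes[dup], pch = 15, col = "red3", cex = 1.2)
  if (any(spc)) ape::nodelabels(node = nodes[spc], pch = 19, col = "green4", cex = 1.2)
  lost <- startsWith(g$label[leaves], "LOST_")
  if (any(lost)) ape::tiplabels(tip = which(lost), pch = 19, col = "grey60", cex = 1.2)
  es <- g$event_support
  if (show_support && !is.null(es)) {
    has <- internal[!is.na(es[internal])]
    if (length(has)) {
      ape::nodelabels(text = sprintf("%.2f", es[has]),
                      node = length(leaves) + match(has, internal),
                      frame = "none", adj = c(1.2, 1.8), cex = 0.7)
    }
  }
  invisible(phy)
}
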