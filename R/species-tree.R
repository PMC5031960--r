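#' The default six-taxon species tree
#'
#' A rooted binary tree over six eudicots used as the fixed frame for
#' reconciliation: Theobroma cacao (`the`, rosid outgroup), Solanum
#' lycopersicum (`tom`, asterid outgroup), Coffea canephora (`cof`,
#' Rubiaceae) and three Apocynaceae — Rhazya stricta (`rha`), Catharanthus
#' roseus (`cra`) and Rauvolfia serpentina (`rsa`). The branching order
#' within the Apocynaceae is not settled; the shipped default places
#' `cra` and `rsa` as sisters and can be overridden by editing the Newick
#' fixture or passing any rooted binary tree. Branch lengths are expected
#' amino-acid substitutions per site.
#'
#' @param path optional path to a Newick file overriding the shipped
#'   fixture.
#' @return A rooted binary `gtree` whose leaves are taxon codes.
#' @examples
#' sp <- species_tree_default()
#' species_taxa(sp)
#' @export
species_tree_default <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_tree.nwk", package = "genetrace")
  g <- gtree_from_phylo(ape::read.tree(path))
  validate_species_tree(g)
  g
}

#' @rdname species_tree_default
#' @param sp a species `gtree`.
#' @export
species_taxa <- function(sp) sort(sp$label[gtree_leaves(sp)])

validate_species_tree <- function(sp) {
  if (!is_binary_gtree(sp)) stop_input("species tree must be rooted and binary")
  taxa <- sp$label[gtree_leaves(sp)]
  if (anyDuplicated(taxa)) stop_input("duplicate taxon codes in species tree")
  invisible(sp)
}

# Precomputed ancestry index for LCA / path queries on a species tree.
species_index <- function(sp) {
  n <- gtree_n(sp)
  depth <- integer(n)
  ord <- gtree_postorder(sp)
  for (v in rev(ord)) {
    p <- sp$parent[v]
    depth[v] <- if (p == 0) 0L else depth[p] + 1L
  }
  leafmap <- setNames(gtree_leaves(sp), sp$label[gtree_leaves(sp)])
  list(tree = sp, depth = depth, leafmap = leafmap)
}

sp_lca <- function(idx, u, v) {
  while (u != v) {
    if (idx$depth[u] < idx$depth[v]) v <- idx$tree$parent[v]
    else u <- idx$tree$parent[u]
  }
  u
}

# Is `a` an ancestor of (or equal to) `b`?
sp_is_ancestor <- function(idx, a, b) {
  while (idx$depth[b] > idx$depth[a]) b <- idx$tree$parent[b]
  a == b
}

# Path from descendant `b` up to (excluding) ancestor `a`: the nodes
# strictly between plus b itself, ordered b -> towards a.
sp_path_up <- function(idx, a, b) {
  out <- integer(0)
  while (b != a) {
    out <- c(out, b)
    b <- idx$tree$parent[b]
  }
  out
}

sp_sibling <- function(idx, v) {
  p <- idx$tree$parent[v]
  if (p == 0) return(NA_integer_)
  setdiff(idx$tree$children[[p]], v)
}

# Human-readable name for a species-tree node (leaf code or clade key).
sp_node_name <- function(sp, v) {
  if (length(sp$children[[v]]) == 0) return(sp$label[v])
  ck <- clade_keys(sp)
  gsub("\\|", "-", ck[v])
}
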