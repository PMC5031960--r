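# LCA reconciliation of a gene tree with the species tree under
# duplication-loss parsimony.

#' Reconcile a gene tree with the species tree
#'
#' Maps every gene-tree node to a species-tree node by the LCA rule
#' (leaves to their species; internal nodes to the LCA of their
#' children's images), labels a node a duplication exactly when some
#' child maps to the same species node, and counts losses along each
#' gene-tree edge as the number of species-tree branches skipped, minus
#' one when the parent is a speciation. The LCA mapping minimizes the
#' total duplication + loss cost over all ancestry-respecting mappings.
#'
#' Leaf labels follow the `species.gene` convention: the species code is
#' the label prefix before the first dot.
#'
#' @param gene_tree a rooted `gtree` (binary or not).
#' @param species_tree a rooted binary species `gtree`.
#' @return An object of class `reconciliation`: list with `mapping`
#'   (gene node -> species node index), `events` (per-node label),
#'   `losses` (tibble: species branch name, edge, count), `dup_count`,
#'   `loss_count`, `cost`, plus the annotated `gene_tree` (events filled
#'   in) and `species_tree`.
#' @examples
#' sp <- read_gtree("((A,B),C);")
#' gt <- read_gtree("((A.a1,C.c1),B.b1);")
#' lca_reconcile(gt, sp)$cost  # 1 duplication + 3 losses
#' @export
lca_reconcile <- function(gene_tree, species_tree) {
  g <- gene_tree
  idx <- species_index(species_tree)
  leaves <- gtree_leaves(g)
  spp <- species_code(g$label[leaves])
  unknown <- !spp %in% names(idx$leafmap)
  if (any(unknown)) {
    stop_input("leaf '", g$label[leaves][unknown][1],
               "' has species code '", spp[unknown][1],
               "' absent from the species tree")
  }
  n <- gtree_n(g)
  mapping <- integer(n)
  mapping[leaves] <- idx$leafmap[spp]
  events <- rep(NA_character_, n)
  ord <- gtree_postorder(g)
  for (v in ord) {
    ch <- g$children[[v]]
    if (length(ch) == 0) next
    m <- mapping[ch[1]]
    for (c in ch[-1]) m <- sp_lca(idx, m, mapping[c])
    mapping[v] <- m
    events[v] <- if (any(mapping[ch] == m)) "duplication" else "speciation"
  }
  # losses per edge: species branches skipped between the images, with
  # the speciation parent consuming one level
  loss_rows <- list()
  loss_count <- 0L
  for (v in ord) {
    for (c in g$children[[v]]) {
      path <- sp_path_up(idx, mapping[v], mapping[c])  # c-image up to v-image
      skipped <- if (events[v] == "speciation") path[-length(path)] else path
      # each skipped step loses the sibling branch at that level
      for (s in skipped) {
        sib <- sp_sibling(idx, s)
        loss_rows[[length(loss_rows) + 1L]] <-
          list(edge_child = c, species_node = sib,
               branch = sp_node_name(species_tree, sib))
        loss_count <- loss_count + 1L
      }
    }
  }
  losses <- if (length(loss_rows)) {
    dplyr::count(dplyr::bind_rows(lapply(loss_rows, tibble::as_tibble)),
                 .data$edge_child, .data$species_node, .data$branch,
                 name = "count")
  } else {
    tibble::tibble(edge_child = integer(), species_node = integer(),
                   branch = character(), count = integer())
  }
  dup_count <- sum(events == "duplication", na.rm = TRUE)
  g$event <- events
  structure(list(
    mapping = mapping, events = events, losses = losses,
    dup_count = as.integer(dup_count), loss_count = loss_count,
    cost = as.integer(dup_count + loss_count),
    gene_tree = g, species_tree = species_tree
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d duplications + %d losses = cost %d>\n",
              x$dup_count, x$loss_count, x$cost))
  invisible(x)
}

#' Graft inferred losses onto a reconciled gene tree
#'
#' Attaches one pseudo-leaf per inferred loss, labelled
#' `LOST_<species branch>`, on the gene-tree edge where the loss was
#' inferred; the original topology is otherwise unchanged. Grafted nodes
#' carry the `loss` event label.
#'
#' @param tree the gene `gtree` the reconciliation was computed from.
#' @param rec a `reconciliation` from [lca_reconcile()].
#' @return A `gtree` with loss leaves attached.
#' @export
graft_losses <- function(tree, rec) {
  if (rec$loss_count == 0) return(rec$gene_tree)
  g <- rec$gene_tree
  # splice one speciation node + loss leaf per inferred loss onto the
  # edge above `edge_child`, working directly on the index vectors
  for (k in seq_len(nrow(rec$losses))) {
    row <- rec$losses[k, ]
    for (j in seq_len(row$count)) {
      c <- row$edge_child
      p <- g$parent[c]
      n <- gtree_n(g)
      inner <- n + 1L  # new speciation node on the edge
      ghost <- n + 2L  # the lost lineage
      g$parent <- c(g$parent, p, inner)
      g$label <- c(g$label, "", paste0("LOST_", row$branch))
      g$length <- c(g$length, g$length[c], 0)
      g$support <- c(g$support, NA_real_, NA_real_)
      g$event <- c(g$event, "speciation", "loss")
      g$children[[inner]] <- c(c, ghost)
      g$children[[ghost]] <- integer(0)
      g$children[[p]][g$children[[p]] == c] <- inner
      g$parent[c] <- inner
      g$length[c] <- 0
    }
  }
  g
}

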