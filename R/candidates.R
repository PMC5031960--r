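# Candidate reconciled trees: threshold contraction x rooting x minimal
# refinement, likelihood + cost selection, consensus, and per-node event
# supports.

# Fit branch lengths of a rooted topology from a distance matrix by
# non-negative least squares on the unrooted topology (phangorn), then
# transfer them back by bipartition.
fit_branch_lengths <- function(g, dm) {
  phy <- gtree_to_phylo(g)
  up <- ape::unroot(phy)
  up$edge.length <- rep(0.1, nrow(up$edge))
  fitted <- suppressWarnings(phangorn::nnls.tree(
    as.dist(dm[up$tip.label, up$tip.label]), up, method = "unrooted"
  ))
  fitted$edge.length[fitted$edge.length < 0] <- 0
  gu <- gtree_from_phylo(fitted)
  len_by_split <- setNames(gu$length, split_keys(gu))
  sk <- split_keys(g)
  root_children <- g$children[[g$root]]
  for (v in seq_len(gtree_n(g))) {
    if (v == g$root) next
    L <- len_by_split[[sk[v]]]
    if (is.null(L) || is.na(L)) L <- 0
    g$length[v] <- if (v %in% root_children) L / 2 else L
  }
  g
}

#' Generate candidate reconciled trees
#'
#' For every support threshold, contracts the weakly supported branches
#' of the input gene tree, enumerates all rootings of the resulting
#' non-binary tree, and computes the minimum duplication+loss binary
#' refinements of each rooted tree. Candidates are deduplicated by
#' rooted topology (multiplicity retained), their branch lengths
#' re-estimated from the alignment distances, and each is scored by
#' reconciliation cost and per-site log-likelihood.
#'
#' @param tree a `gtree` with bootstrap supports (rooted or unrooted).
#' @param species_tree a rooted binary species `gtree`.
#' @param alignment named character vector or `AAStringSet` over the
#'   gene-tree leaves.
#' @param thresholds bootstrap thresholds to scan (default 20,30,...,90).
#' @param max_solutions maximal number of minimal refinements kept per
#'   (threshold, rooting).
#' @param cap maximal number of distinct candidates; beyond it the
#'   best-cost candidates are kept with a warning.
#' @param subs_model,gamma_categories,gamma_alpha likelihood settings
#'   (see [felsenstein_loglik()]).
#' @return A tibble with one row per distinct candidate topology:
#'   `candidate`, `tree` (list of `gtree`), `topo_key`, `n`
#'   (multiplicity), `dup_count`, `loss_count`, `cost`, `loglik`,
#'   `site_ll` (list), `origins` (list of tibbles: threshold, rooting,
#'   refinement).
#' @export
generate_candidates <- function(tree, species_tree, alignment,
                                thresholds = seq(20, 90, by = 10),
                                max_solutions = 8L, cap = 200L,
                                subs_model = "LG", gamma_categories = 4L,
                                gamma_alpha = 1) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  dm <- protein_distance_matrix(alignment)
  found <- list()  # topo_key -> list(tree, origins)
  for (th in thresholds) {
    ct <- contract_low_support(tree, th)
    rootings <- enumerate_rootings(ct)
    for (ri in seq_along(rootings)) {
      sols <- resolve_polytomies_min_cost(rootings[[ri]], species_tree,
                                          dist = dm, max_solutions = max_solutions)
      for (si in seq_along(sols)) {
        key <- topo_key(sols[[si]])
        origin <- tibble::tibble(threshold = th, rooting = ri, refinement = si)
        if (is.null(found[[key]])) {
          found[[key]] <- list(tree = sols[[si]], origins = list(origin))
        } else {
          found[[key]]$origins <- c(found[[key]]$origins, list(origin))
        }
      }
    }
  }
  rows <- lapply(names(found), function(key) {
    entry <- found[[key]]
    g <- fit_branch_lengths(entry$tree, dm)
    rec <- lca_reconcile(g, species_tree)
    ll <- felsenstein_loglik(rec$gene_tree, alignment, subs_model = subs_model,
                             gamma_categories = gamma_categories,
                             gamma_alpha = gamma_alpha)
    tibble::tibble(
      tree = list(rec$gene_tree), topo_key = key,
      n = length(entry$origins),
      dup_count = rec$dup_count, loss_count = rec$loss_count,
      cost = rec$cost, loglik = ll$total, site_ll = list(ll$site),
      origins = list(dplyr::bind_rows(entry$origins))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$cost, dplyr::desc(.data$loglik), .data$topo_key)
  if (nrow(out) > cap) {
    warn(sprintf("candidate explosion: keeping the %d best-cost of %d candidates",
                 cap, nrow(out)))
    out <- out[seq_len(cap), ]
  }
  out$candidate <- seq_len(nrow(out))
  dplyr::relocate(out, "candidate")
}

#' Select the best candidates by likelihood and reconciliation cost
#'
#' Keeps the candidates that survive the SH test against the best
#' likelihood (via [sh_filter()]) and, among the survivors, those with
#' the minimal reconciliation cost.
#'
#' @param candidates a candidate tibble from [generate_candidates()].
#' @param alpha SH significance level (default 0.05).
#' @param n_rell RELL replicates.
#' @param seed integer seed for the RELL resampling.
#' @return The filtered candidate tibble; SH p-values are kept in the
#'   `sh_p` column.
#' @export
select_best <- function(candidates, alpha = 0.05, n_rell = 1000L, seed = 1L) {
  if (nrow(candidates) == 0) stop_input("no candidates")
  if (nrow(candidates) == 1) {
    candidates$sh_p <- 1
    return(candidates)
  }
  keep <- sh_filter(do.call(rbind, candidates$site_ll),
                    n_rell = n_rell, seed = seed, alpha = alpha)
  candidates$sh_p <- attr(keep, "p_values")
  surv <- candidates[as.integer(keep), ]
  surv[surv$cost == min(surv$cost), ]
}

#' Extended majority-rule consensus of rooted gene trees
#'
#' Greedy consensus: clades are added in decreasing frequency (ties by
#' clade size then label order) as long as they are compatible with the
#' clades already accepted. Every clade with frequency above 1/2 is
#' therefore in the consensus. Clade frequencies become supports
#' (percent).
#'
#' @param trees a list of rooted `gtree` objects on the same leaf set.
#' @param weights optional nonnegative weights (e.g. candidate
#'   multiplicities).
#' @return A rooted (possibly non-binary) `gtree`.
#' @export
consensus_extended_majority <- function(trees, weights = NULL) {
  if (length(trees) == 0) stop_input("no trees")
  weights <- weights %||% rep(1, length(trees))
  leafsets <- lapply(trees, function(g) sort(g$label[gtree_leaves(g)]))
  if (length(unique(vapply(leafsets, paste, "", collapse = "|"))) != 1) {
    stop_input("trees must share the same leaf set")
  }
  leaves <- leafsets[[1]]
  freq <- list()
  for (i in seq_along(trees)) {
    g <- trees[[i]]
    keys <- unique(clade_keys(g)[gtree_internal(g)])
    for (k in keys) freq[[k]] <- (freq[[k]] %||% 0) + weights[i]
  }
  total <- sum(weights)
  keys <- names(freq)
  f <- unlist(freq) / total
  sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
  ord <- order(-f, -sizes, keys)
  accepted <- list()  # list of character vectors (leaf sets)
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0 || i == length(a) || i == length(b)
  }
  for (k in ord) {
    set <- strsplit(keys[k], "|", fixed = TRUE)[[1]]
    if (all(vapply(accepted, compatible, TRUE, b = set))) {
      accepted[[length(accepted) + 1L]] <- set
      names(accepted)[length(accepted)] <- sprintf("%.6f", f[k])
    }
  }
  # ensure the root clade is present
  if (!any(vapply(accepted, function(s) length(s) == length(leaves), TRUE))) {
    accepted <- c(accepted, setNames(list(leaves), "1.000000"))
  }
  # assemble the laminar family into a tree
  supports <- as.numeric(names(accepted))
  o <- order(lengths(accepted))
  accepted <- accepted[o]
  supports <- supports[o]
  n_cl <- length(accepted)
  nodes_n <- length(leaves) + n_cl
  parent <- integer(nodes_n)
  label <- c(leaves, rep("", n_cl))
  support <- rep(NA_real_, nodes_n)
  clade_of <- function(set) {
    for (j in seq_len(n_cl)) {
      if (length(accepted[[j]]) > length(set) && all(set %in% accepted[[j]])) {
        return(length(leaves) + j)
      }
    }
    0L
  }
  for (i in seq_along(leaves)) parent[i] <- clade_of(leaves[i])
  for (j in seq_len(n_cl)) {
    parent[length(leaves) + j] <- clade_of(accepted[[j]])
    support[length(leaves) + j] <- round(100 * supports[j])
  }
  g <- new_gtree(parent, label, support = support)
  g$support[g$root] <- NA_real_
  g
}

# symmetric clade-set difference between two rooted trees
clade_rf <- function(a, b) {
  ka <- unique(clade_keys(a)[gtree_internal(a)])
  kb <- unique(clade_keys(b)[gtree_internal(b)])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Final reconciled tree with per-node event supports
#'
#' Among the selected best candidates, picks the one closest (clade
#' symmetric difference) to their extended majority-rule consensus, ties
#' broken by likelihood. Each internal node of the final tree gets an
#' event support: the multiplicity-weighted fraction of all candidate
#' replicates containing the same clade with the same inferred event.
#' When an alignment is supplied, clade bootstrap values are also
#' recomputed on the final topology.
#'
#' @param best the tibble from [select_best()].
#' @param all_candidates the full tibble from [generate_candidates()].
#' @param alignment optional alignment for recomputing clade bootstraps.
#' @param n_boot,seed bootstrap settings when `alignment` is given.
#' @return A list with `tree` (final `gtree`, events filled, clade
#'   bootstraps as supports), `consensus`, `node_support` (tibble:
#'   clade, event, support) and `candidate` (the chosen row index in
#'   `best`).
#' @export
final_tree_and_support <- function(best, all_candidates, alignment = NULL,
                                   n_boot = 100L, seed = 1L) {
  if (nrow(best) == 0) stop_input("`best` is empty")
  cons <- consensus_extended_majority(best$tree, weights = best$n)
  rf <- vapply(best$tree, clade_rf, 0, b = cons)
  pick <- order(rf, -best$loglik)[1]
  final <- best$tree[[pick]]

  # event support over all replicates, weighted by multiplicity
  tally <- list()
  total <- sum(all_candidates$n)
  for (i in seq_len(nrow(all_candidates))) {
    g <- all_candidates$tree[[i]]
    ck <- clade_keys(g)
    for (v in gtree_internal(g)) {
      key <- paste0(ck[v], "@", g$event[v])
      tally[[key]] <- (tally[[key]] %||% 0) + all_candidates$n[i]
    }
  }
  ckf <- clade_keys(final)
  rows <- lapply(gtree_internal(final), function(v) {
    key <- paste0(ckf[v], "@", final$event[v])
    tibble::tibble(node = v, clade = ckf[v], event = final$event[v],
                   support = (tally[[key]] %||% 0) / total)
  })
  node_support <- dplyr::bind_rows(rows)
  final$event_support <- rep(NA_real_, gtree_n(final))
  final$event_support[node_support$node] <- node_support$support

  if (!is.null(alignment)) {
    bs <- bootstrap_supports(alignment, n_reps = n_boot, seed = seed)
    sup_by_split <- setNames(bs$support, split_keys(bs))
    skf <- split_keys(final)
    n_leaves <- length(gtree_leaves(final))
    for (v in setdiff(gtree_internal(final), final$root)) {
      side <- length(strsplit(skf[v], "|", fixed = TRUE)[[1]])
      if (min(side, n_leaves - side) < 2) {
        final$support[v] <- NA_real_  # trivial split (root edge)
        next
      }
      s <- sup_by_split[[skf[v]]]
      final$support[v] <- if (is.null(s) || is.na(s)) 0 else s
    }
  }
  list(tree = final, consensus = cons, node_support = node_support,
       candidate = pick)
}

#' Per-species homolog counts and event totals across families
#'
#' Summarizes final reconciled trees into the table behind per-species
#' homolog-count histograms: one row per family with the number of
#' genes per species and the inferred duplication and loss totals.
#'
#' @param families a named list; each element either a `reconciliation`
#'   or a list with elements `tree` (a `gtree`), `dup_count`,
#'   `loss_count`.
#' @param species character vector of species codes defining the
#'   columns (default: the union observed).
#' @return A tibble: `family`, one count column per species,
#'   `dup_count`, `loss_count`.
#' @export
family_report <- function(families, species = NULL) {
  if (length(families) == 0) {
    return(tibble::tibble(family = character(), dup_count = integer(),
                          loss_count = integer()))
  }
  if (is.null(names(families))) {
    names(families) <- paste0("family", seq_along(families))
  }
  rows <- lapply(names(families), function(nm) {
    x <- families[[nm]]
    tree <- if (inherits(x, "reconciliation")) x$gene_tree else x$tree
    labs <- tree$label[gtree_leaves(tree)]
    labs <- labs[!startsWith(labs, "LOST_")]
    spp <- species_code(labs)
    counts <- table(spp)
    tibble::tibble(family = nm, species = names(counts),
                   n_genes = as.integer(counts),
                   dup_count = if (inherits(x, "reconciliation")) x$dup_count else x$dup_count,
                   loss_count = if (inherits(x, "reconciliation")) x$loss_count else x$loss_count)
  })
  long <- dplyr::bind_rows(rows)
  species <- species %||% sort(unique(long$species))
  wide <- tidyr::pivot_wider(long, names_from = "species",
                             values_from = "n_genes", values_fill = 0L)
  missing_cols <- setdiff(species, names(wide))
  for (s in missing_cols) wide[[s]] <- 0L
  dplyr::relocate(wide, "family", dplyr::all_of(species),
                  "dup_count", "loss_count")
}
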