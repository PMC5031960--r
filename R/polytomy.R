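# Minimum duplication+loss resolution of polytomies by dynamic
# programming over the species tree (cost-vector method).
#
# For a polytomy whose children map to species nodes inside the subtree
# of r = LCA(children images), define c_s(k) = minimal dup+loss cost of
# the part of the resolved subtree at-or-below species node s given k
# gene lineages entering s. With n(s) children of the polytomy mapped
# exactly to s and l = k'' - n(s) lineages passing the speciation at s:
#
#   c_s(k) = min_{k'' >= n(s)} |k'' - k| + c_s1(l) + c_s2(l)
#
# (leaf species force k'' = n(s); k = 0 is feasible only when no genes
# occur at or below s). The polytomy's minimal cost is c_r(1), and
# resolutions minimize the global reconciliation cost independently per
# polytomy because a refinement never changes its root's LCA image.

# --- DP over one polytomy ------------------------------------------------

polytomy_dp <- function(idx, r, counts, K) {
  sp <- idx$tree
  sub <- integer(0)  # species subtree of r, postorder
  collect <- function(v) {
    for (c in sp$children[[v]]) collect(c)
    sub <<- c(sub, v)
  }
  collect(r)
  genes_below <- logical(gtree_n(sp))
  C <- matrix(Inf, nrow = gtree_n(sp), ncol = K + 1)  # C[s, k+1]
  KPP <- matrix(NA_integer_, nrow = gtree_n(sp), ncol = K + 1)
  for (s in sub) {
    ch <- sp$children[[s]]
    n_s <- counts[s]
    genes_below[s] <- n_s > 0 || (length(ch) > 0 && any(genes_below[ch]))
    C[s, 1] <- if (genes_below[s]) Inf else 0
    KPP[s, 1] <- 0L
    for (k in 1:K) {
      if (length(ch) == 0) {
        C[s, k + 1] <- abs(k - n_s)
        KPP[s, k + 1] <- n_s
      } else {
        best <- Inf; best_kpp <- NA_integer_
        for (kpp in n_s:K) {
          l <- kpp - n_s
          base <- C[ch[1], l + 1] + C[ch[2], l + 1]
          if (!is.finite(base)) next
          v <- abs(kpp - k) + base
          if (v < best) {
            best <- v
            best_kpp <- kpp
          }
        }
        C[s, k + 1] <- best
        KPP[s, k + 1] <- best_kpp
      }
    }
  }
  list(C = C, KPP = KPP)
}

# --- choice plans for enumerating alternative optimal join orders --------
# A plan is a mixed-radix digit vector; each choice point consumes one
# digit (defaulting to the first option) and records its arity so the
# caller can advance to the next plan.

make_chooser <- function(plan) {
  env <- new.env(parent = emptyenv())
  env$plan <- plan
  env$pos <- 0L
  env$arities <- integer(0)
  env$choose <- function(n_options) {
    env$pos <- env$pos + 1L
    env$arities[env$pos] <- n_options
    if (env$pos <= length(env$plan)) min(env$plan[env$pos], n_options) else 1L
  }
  env
}

next_plan <- function(plan, arities) {
  n <- length(arities)
  if (n == 0) return(NULL)
  digits <- c(plan, rep(1L, max(0L, n - length(plan))))[seq_len(n)]
  for (i in rev(seq_len(n))) {
    if (digits[i] < arities[i]) {
      digits[i] <- digits[i] + 1L
      return(digits[seq_len(i)])
    }
  }
  NULL
}

# --- reconstruction ------------------------------------------------------

item_leaves <- function(item) {
  if (is.null(item)) return(character(0))
  if (length(item$children) == 0) return(item$label)
  unlist(lapply(item$children, item_leaves))
}

# Candidate join pairs ordered by an NJ-style criterion on `dist`
# (Q-score under average linkage) or lexicographically when dist is NULL.
ordered_pairs <- function(items, dist) {
  t <- length(items)
  pairs <- which(upper.tri(matrix(0, t, t)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (is.null(dist) || t <= 2) return(pairs)
  lv <- lapply(items, item_leaves)
  have <- vapply(lv, function(x) length(x) > 0 && all(x %in% rownames(dist)), TRUE)
  if (!all(have)) return(pairs)
  dd <- matrix(0, t, t)
  for (i in 1:(t - 1)) for (j in (i + 1):t) {
    dd[i, j] <- dd[j, i] <- mean(dist[lv[[i]], lv[[j]], drop = FALSE])
  }
  rs <- rowSums(dd)
  q <- (t - 2) * dd - outer(rs, rs, "+")
  score <- q[cbind(pairs[, 1], pairs[, 2])]
  pairs[order(score, pairs[, 1], pairs[, 2]), , drop = FALSE]
}

join_two <- function(a, b, event) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  rlist_node(length = 0, event = event, children = list(a, b))
}

# Combine `items` (rlists or NULLs for lineages lost below) down to
# `k_target` via duplication joins; prefers joining live subtrees.
join_dup <- function(items, k_target, dist, chooser) {
  while (length(items) > k_target) {
    real <- which(!vapply(items, is.null, TRUE))
    use <- if (length(real) >= 2) real else seq_along(items)
    pairs <- ordered_pairs(items[use], dist)
    pick <- chooser$choose(nrow(pairs))
    i <- use[pairs[pick, 1]]
    j <- use[pairs[pick, 2]]
    items[i] <- list(join_two(items[[i]], items[[j]], "duplication"))
    items <- items[-j]
  }
  items
}

# Build one optimal resolution of a polytomy. `items_at` holds the
# (already resolved) child subtrees grouped by species image.
build_resolution <- function(idx, r, counts, K, dp, items_at, dist, chooser) {
  sp <- idx$tree
  build <- function(s, k) {
    if (k == 0) return(list())
    ch <- sp$children[[s]]
    kpp <- dp$KPP[s, k + 1]
    items <- if (length(ch) == 0) {
      items_at[[as.character(s)]] %||% list()
    } else {
      l <- kpp - counts[s]
      A <- build(ch[1], l)
      B <- build(ch[2], l)
      paired <- lapply(seq_len(l), function(i) {
        join_two(A[[i]], B[[i]], "speciation")
      })
      c(paired, items_at[[as.character(s)]] %||% list())
    }
    if (length(items) > k) items <- join_dup(items, k, dist, chooser)
    if (length(items) < k) items <- c(items, vector("list", k - length(items)))
    items
  }
  build(r, 1L)[[1]]
}

# --- public operation ----------------------------------------------------

#' Resolve polytomies at minimum duplication+loss cost
#'
#' Replaces every polytomy of a rooted gene tree by a binary subtree
#' such that the total reconciliation cost against the species tree is
#' minimal over all binary refinements. The minimum is found by dynamic
#' programming over the species tree (cost-vector method), not by
#' enumeration; when several optimal resolutions exist, up to
#' `max_solutions` distinct ones are constructed by varying the join
#' order, guided NJ-style by `dist` when a distance matrix over the gene
#' leaves is supplied.
#'
#' @param tree a rooted `gtree`, possibly non-binary.
#' @param species_tree a rooted binary species `gtree`.
#' @param dist optional distance matrix (row/col names = leaf labels)
#'   used to order equal-cost joins.
#' @param max_solutions maximum number of resolutions returned.
#' @return A list of rooted binary `gtree` objects, each a refinement of
#'   `tree` attaining the minimal reconciliation cost; the minimum cost
#'   is attached as attribute `min_cost`.
#' @export
resolve_polytomies_min_cost <- function(tree, species_tree, dist = NULL,
                                        max_solutions = 1L) {
  if (max_solutions < 1) stop_input("max_solutions must be >= 1")
  rec0 <- lca_reconcile(tree, species_tree)
  if (is_binary_gtree(tree)) {
    out <- list(rec0$gene_tree)
    attr(out, "min_cost") <- rec0$cost
    return(out)
  }
  idx <- species_index(species_tree)
  mapping <- rec0$mapping
  dp_cache <- list()

  build_full <- function(chooser) {
    rec <- function(v) {
      ch <- tree$children[[v]]
      if (length(ch) == 0) {
        return(rlist_node(label = tree$label[v], length = tree$length[v],
                          support = tree$support[v], event = tree$event[v]))
      }
      kids <- lapply(ch, rec)  # children resolved bottom-up first
      if (length(ch) == 2) {
        return(rlist_node(length = tree$length[v], support = tree$support[v],
                          children = kids))
      }
      K <- length(ch)
      r <- mapping[v]
      counts <- integer(gtree_n(species_tree))
      items_at <- list()
      for (j in seq_along(ch)) {
        s <- mapping[ch[j]]
        counts[s] <- counts[s] + 1L
        items_at[[as.character(s)]] <-
          c(items_at[[as.character(s)]] %||% list(), kids[j])
      }
      key <- as.character(v)
      if (is.null(dp_cache[[key]])) {
        dp_cache[[key]] <<- polytomy_dp(idx, r, counts, K)
      }
      sub <- build_resolution(idx, r, counts, K, dp_cache[[key]],
                              items_at, dist, chooser)
      sub$length <- tree$length[v]
      sub$support <- tree$support[v]
      sub
    }
    rlist_to_gtree(rec(tree$root))
  }

  seen <- character(0)
  out <- list()
  plan <- integer(0)
  repeat {
    chooser <- make_chooser(plan)
    g <- build_full(chooser)
    key <- topo_key(g)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- g
    }
    if (length(out) >= max_solutions) break
    plan <- next_plan(plan, chooser$arities)
    if (is.null(plan)) break
  }
  attr(out, "min_cost") <- lca_reconcile(out[[1]], species_tree)$cost
  out
}
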