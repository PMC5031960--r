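# Independent oracles used to validate the package's algorithms:
# written against the definitions, not against the implementation paths.

# --- genomes as element sets, BFS over the DCJ operation graph -----------

# element-set view of a genome: list of sorted integer vectors (length 2 =
# adjacency, length 1 = telomere) over extremities 1..2n
oracle_elements <- function(g, universe = genome_genes(g)) {
  p <- genetrace:::genome_partner(g, universe)
  els <- list()
  for (e in seq_along(p)) {
    if (p[e] == 0L) els[[length(els) + 1L]] <- e
    else if (p[e] > e) els[[length(els) + 1L]] <- c(e, p[e])
  }
  els
}

oracle_key <- function(els) {
  mins <- vapply(els, min, 0L)
  paste(vapply(els[order(mins)], paste, "", collapse = "-"), collapse = "|")
}

# every genome one DCJ operation away, by cutting one or two elements and
# rejoining their ends differently
oracle_neighbors <- function(els) {
  out <- list()
  add <- function(base, new_els) {
    out[[length(out) + 1L]] <<- c(base, new_els)
  }
  m <- length(els)
  for (i in seq_len(m)) {
    X <- els[[i]]
    if (length(X) == 2) {
      add(els[-i], list(X[1], X[2]))  # split an adjacency
    }
    if (i < m) {
      for (j in (i + 1):m) {
        Y <- els[[j]]
        rest <- els[-c(i, j)]
        if (length(X) == 2 && length(Y) == 2) {
          add(rest, list(sort(c(X[1], Y[1])), sort(c(X[2], Y[2]))))
          add(rest, list(sort(c(X[1], Y[2])), sort(c(X[2], Y[1]))))
        } else if (length(X) == 2 && length(Y) == 1) {
          add(rest, list(sort(c(X[1], Y)), X[2]))
          add(rest, list(sort(c(X[2], Y)), X[1]))
        } else if (length(X) == 1 && length(Y) == 2) {
          add(rest, list(sort(c(Y[1], X)), Y[2]))
          add(rest, list(sort(c(Y[2], X)), Y[1]))
        } else {
          add(rest, list(sort(c(X, Y))))
        }
      }
    }
  }
  out
}

# bidirectional BFS shortest path in the DCJ operation graph
oracle_dcj_bfs <- function(a, b) {
  universe <- genome_genes(a)
  start <- oracle_elements(a, universe)
  goal <- oracle_elements(b, universe)
  ks <- oracle_key(start); kg <- oracle_key(goal)
  if (ks == kg) return(0L)
  fwd <- new.env(parent = emptyenv()); assign(ks, 0L, envir = fwd)
  bwd <- new.env(parent = emptyenv()); assign(kg, 0L, envir = bwd)
  frontier_f <- list(start); frontier_b <- list(goal)
  d_f <- 0L; d_b <- 0L
  repeat {
    expand_fwd <- length(frontier_f) <= length(frontier_b)
    frontier <- if (expand_fwd) frontier_f else frontier_b
    mine <- if (expand_fwd) fwd else bwd
    other <- if (expand_fwd) bwd else fwd
    d <- (if (expand_fwd) d_f else d_b) + 1L
    nxt <- list()
    for (els in frontier) {
      for (nb in oracle_neighbors(els)) {
        k <- oracle_key(nb)
        if (!is.null(mine[[k]])) next
        if (!is.null(other[[k]])) return(d + other[[k]])
        assign(k, d, envir = mine)
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    if (length(nxt) == 0) stop("disconnected DCJ graph (bug)")
    if (expand_fwd) {
      frontier_f <- nxt; d_f <- d
    } else {
      frontier_b <- nxt; d_b <- d
    }
  }
}

# exhaustive DCJ median score: minimum over every genome on the universe
oracle_median_score <- function(a, b, c) {
  universe <- genome_genes(a)
  pa <- genetrace:::genome_partner(a, universe)
  pb <- genetrace:::genome_partner(b, universe)
  pc <- genetrace:::genome_partner(c, universe)
  n2 <- length(pa)
  best <- Inf
  p <- integer(n2)
  assigned <- logical(n2)
  dist3 <- function(p) {
    genetrace:::dist_partner(p, pa) + genetrace:::dist_partner(p, pb) +
      genetrace:::dist_partner(p, pc)
  }
  rec <- function() {
    e <- which(!assigned)[1]
    if (is.na(e)) {
      s <- dist3(p)
      if (s < best) best <<- s
      return()
    }
    assigned[e] <<- TRUE
    p[e] <<- 0L
    rec()
    for (f in which(!assigned)) {
      if (f <= e) next
      assigned[f] <<- TRUE
      p[e] <<- f; p[f] <<- e
      rec()
      assigned[f] <<- FALSE
      p[f] <<- 0L
    }
    assigned[e] <<- FALSE
    p[e] <<- 0L
  }
  rec()
  best
}

random_test_genome <- function(n_genes, seed, name = "g") {
  n_chr <- 1L + (seed %% min(2L, n_genes))
  circ <- (seed %% 3L) == 0L
  random_genome(n_genes, n_chromosomes = n_chr, circular = circ,
                seed = seed, name = name)
}

# --- affine-gap local alignment DP (independent of Biostrings) -----------

oracle_sw_score <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  gap1 <- gap_open + gap_extend  # cost of the first gapped column
  H <- matrix(0, n + 1, m + 1)   # best local score ending at (i, j)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consume B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consume A)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap1, E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap1, F[i, j + 1] - gap_extend)
      diag <- H[i, j] + mat[A[i], B[j]]
      H[i + 1, j + 1] <- max(0, diag, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# --- reconciliation: minimum cost over all ancestry-respecting mappings --

oracle_reconcile_cost <- function(gene_tree, species_tree) {
  g <- gene_tree
  idx <- genetrace:::species_index(species_tree)
  sp <- species_tree
  leaves <- genetrace:::gtree_leaves(g)
  spp <- genetrace:::species_code(g$label[leaves])
  M <- integer(genetrace:::gtree_n(g))
  M[leaves] <- idx$leafmap[spp]
  ord <- genetrace:::gtree_postorder(g)
  internal <- ord[lengths(g$children[ord]) > 0]
  ancestors_of <- function(s) {
    out <- s
    while (sp$parent[s] > 0) {
      s <- sp$parent[s]
      out <- c(out, s)
    }
    out
  }
  cost_of <- function() {
    total <- 0
    for (v in internal) {
      ch <- g$children[[v]]
      l <- M[ch[1]]
      for (c in ch[-1]) l <- genetrace:::sp_lca(idx, l, M[c])
      spec <- M[v] == l && !any(M[ch] == M[v])
      if (!spec) total <- total + 1  # duplication
      for (c in ch) {
        k <- idx$depth[M[c]] - idx$depth[M[v]]
        total <- total + max(0, k - as.integer(spec))
      }
    }
    total
  }
  best <- Inf
  assign_node <- function(pos) {
    if (pos > length(internal)) {
      best <<- min(best, cost_of())
      return()
    }
    v <- internal[pos]
    ch <- g$children[[v]]
    l <- M[ch[1]]
    for (c in ch[-1]) l <- genetrace:::sp_lca(idx, l, M[c])
    for (s in ancestors_of(l)) {
      M[v] <<- s
      assign_node(pos + 1)
    }
    M[v] <<- 0L
  }
  assign_node(1)
  best
}

# --- all binary refinements of a (possibly nested) multifurcating tree ---

enumerate_refinements <- function(g) {
  rl <- genetrace:::gtree_to_rlist(g)
  # all rooted binary shapes over a list of subtrees, by edge insertion
  all_binary <- function(items) {
    if (length(items) == 1) return(list(items[[1]]))
    if (length(items) == 2) {
      return(list(genetrace:::rlist_node(children = items)))
    }
    shorter <- all_binary(items[-length(items)])
    new_item <- items[[length(items)]]
    out <- list()
    insert_everywhere <- function(node, item) {
      res <- list(genetrace:::rlist_node(children = list(node, item)))
      if (length(node$children) == 2) {
        for (ci in 1:2) {
          for (sub in insert_everywhere(node$children[[ci]], item)) {
            nn <- node
            nn$children[[ci]] <- sub
            res <- c(res, list(nn))
          }
        }
      }
      res
    }
    for (t in shorter) out <- c(out, insert_everywhere(t, new_item))
    out
  }
  refine <- function(node) {
    if (length(node$children) == 0) return(list(node))
    kids_options <- lapply(node$children, refine)
    combos <- list(list())
    for (opts in kids_options) {
      combos <- unlist(lapply(combos, function(cmb) {
        lapply(opts, function(o) c(cmb, list(o)))
      }), recursive = FALSE)
    }
    out <- list()
    for (cmb in combos) {
      if (length(cmb) <= 2) {
        nn <- node
        nn$children <- cmb
        out <- c(out, list(nn))
      } else {
        for (shape in all_binary(cmb)) {
          shape$label <- node$label
          out <- c(out, list(shape))
        }
      }
    }
    out
  }
  lapply(refine(rl), genetrace:::rlist_to_gtree)
}

# --- brute-force likelihood: explicit sum over interior states -----------

oracle_loglik <- function(tree, alignment, subs_model = "LG") {
  mod <- genetrace:::aa_model(subs_model)
  g <- tree
  internal <- genetrace:::gtree_internal(g)
  leaves <- genetrace:::gtree_leaves(g)
  chars <- lapply(g$label[leaves], function(l) {
    match(strsplit(alignment[[l]], "")[[1]], genetrace:::.aa_alphabet)
  })
  names(chars) <- as.character(leaves)
  S <- length(chars[[1]])
  P <- lapply(seq_len(genetrace:::gtree_n(g)), function(v) {
    if (v == g$root) return(NULL)
    t <- g$length[v]
    genetrace:::aa_pmatrix(mod, ifelse(is.na(t), 0, t))
  })
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- as.character(internal)
  site_ll <- numeric(S)
  for (s in seq_len(S)) {
    state_of <- function(v) {
      if (v %in% leaves) rep(chars[[as.character(v)]][s], nrow(grid))
      else grid[, as.character(v)]
    }
    prob <- mod$pi[grid[, as.character(g$root)]]
    for (v in seq_len(genetrace:::gtree_n(g))) {
      if (v == g$root) next
      prob <- prob * P[[v]][cbind(state_of(g$parent[v]), state_of(v))]
    }
    site_ll[s] <- log(sum(prob))
  }
  site_ll
}
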