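#' Simulate a gene family by a birth-death process along a species tree
#'
#' Each gene lineage evolves independently in continuous time along the
#' species tree, with branch length (expected substitutions/site) as the
#' exposure: duplications arise at `birth_rate` and losses at `death_rate`
#' per lineage per branch-length unit. Lineages split at every speciation.
#' Extinct lineages are pruned from the emitted gene tree but every death
#' event is logged and counted in `true_loss_count`; `true_dup_count`
#' counts the duplication nodes that survive in the pruned tree. The full
#' event log is returned so the simulation can be replayed and audited.
#'
#' @param species_tree a rooted binary species `gtree`
#'   (default [species_tree_default()]).
#' @param birth_rate,death_rate nonnegative event rates per branch-length
#'   unit.
#' @param root_copies number of gene copies at the species root
#'   (`>= 2` forces `root_copies - 1` duplications at the root).
#' @param seed integer seed; the simulation is deterministic given it.
#' @return An object of class `simulated_family`: a list with
#'   `gene_tree_true` (a `gtree` with `duplication`/`speciation` event
#'   labels, `NULL` when the family went extinct), `true_dup_count`,
#'   `true_loss_count`, `locus_map` (tibble: gene_id, species, locus_id,
#'   isoform_id), `events` (the replayable log), `sequences` (`NULL` until
#'   [evolve_sequences()] is used) and `empty`.
#' @examples
#' fam <- simulate_gene_family(birth_rate = 0.3, death_rate = 0, seed = 7)
#' fam$true_dup_count
#' @export
simulate_gene_family <- function(species_tree = species_tree_default(),
                                 birth_rate = 0.3, death_rate = 0.1,
                                 root_copies = 1L, seed) {
  if (birth_rate < 0 || death_rate < 0) stop_input("rates must be >= 0")
  if (root_copies < 1) stop_input("root_copies must be >= 1")
  validate_species_tree(species_tree)
  sp <- species_tree

  ev <- new.env(parent = emptyenv())
  ev$rows <- list()
  ev$next_id <- 1L
  new_lineage <- function() {
    id <- ev$next_id
    ev$next_id <- id + 1L
    id
  }
  log_event <- function(lineage, type, species_node, t, c1 = NA_integer_, c2 = NA_integer_) {
    ev$rows[[length(ev$rows) + 1L]] <-
      list(lineage = lineage, type = type, species_node = species_node,
           time = t, child1 = c1, child2 = c2)
  }

  total_rate <- birth_rate + death_rate

  # lineage arriving at species node `v` (time measured within branches)
  at_node <- function(v, lineage) {
    ch <- sp$children[[v]]
    if (length(ch) == 0) {
      log_event(lineage, "leaf", v, 0)
      return(rlist_node(label = sp$label[v], length = 0, event = NA_character_))
    }
    l1 <- new_lineage(); l2 <- new_lineage()
    log_event(lineage, "speciation", v, 0, l1, l2)
    bl <- function(w) if (is.na(sp$length[w])) 0 else sp$length[w]
    k1 <- along_branch(ch[1], bl(ch[1]), l1)
    k2 <- along_branch(ch[2], bl(ch[2]), l2)
    join_children(k1, k2, "speciation", 0)
  }

  # lineage travelling along the branch above species node `v` with
  # `t_left` exposure remaining; returns an rlist node (length = time
  # since the caller's node) or NULL when the lineage went extinct.
  along_branch <- function(v, t_left, lineage) {
    elapsed <- 0
    repeat {
      dt <- if (total_rate > 0) rexp(1, total_rate) else Inf
      if (dt >= t_left) {
        node <- at_node(v, lineage)
        if (is.null(node)) return(NULL)
        node$length <- node$length + elapsed + t_left
        return(node)
      }
      elapsed <- elapsed + dt
      t_left <- t_left - dt
      if (runif(1) < birth_rate / total_rate) {
        l1 <- new_lineage(); l2 <- new_lineage()
        log_event(lineage, "birth", v, elapsed, l1, l2)
        k1 <- along_branch(v, t_left, l1)
        k2 <- along_branch(v, t_left, l2)
        node <- join_children(k1, k2, "duplication", 0)
        if (is.null(node)) return(NULL)
        node$length <- node$length + elapsed
        return(node)
      } else {
        log_event(lineage, "death", v, elapsed)
        return(NULL)
      }
    }
  }

  # combine two (possibly extinct) children below an event node; splice
  # pass-through nodes so the pruned tree keeps only real events
  join_children <- function(k1, k2, event, len) {
    alive <- Filter(Negate(is.null), list(k1, k2))
    if (length(alive) == 0) return(NULL)
    if (length(alive) == 1) {
      node <- alive[[1]]
      node$length <- node$length + len
      return(node)
    }
    rlist_node(length = len, event = event, children = alive)
  }

  run <- function() {
    copies <- lapply(seq_len(root_copies), function(i) at_node(sp$root, new_lineage()))
    copies <- Filter(Negate(is.null), copies)
    if (length(copies) == 0) return(NULL)
    tree <- copies[[1]]
    for (k in copies[-1]) {
      tree <- rlist_node(length = 0, event = "duplication", children = list(tree, k))
    }
    tree$length <- NA_real_
    tree
  }

  rl <- with_seed(seed, run())
  events <- dplyr::bind_rows(lapply(ev$rows, tibble::as_tibble))

  if (is.null(rl)) {
    return(structure(list(
      gene_tree_true = NULL, sequences = NULL,
      true_dup_count = 0L, true_loss_count = sum(events$type == "death"),
      locus_map = tibble::tibble(gene_id = character(), species = character(),
                                 locus_id = character(), isoform_id = character()),
      events = events, empty = TRUE,
      params = list(birth_rate = birth_rate, death_rate = death_rate,
                    root_copies = root_copies, seed = seed),
      species_tree = sp
    ), class = "simulated_family"))
  }

  g <- rlist_to_gtree(rl)
  # label surviving genes spp.g<k>, numbering left-to-right within species
  leaves <- gtree_leaves(g)
  spp <- g$label[leaves]
  counts <- integer(0)
  for (i in seq_along(leaves)) {
    s <- spp[i]
    counts[s] <- (if (is.na(counts[s])) 0L else counts[s]) + 1L
    g$label[leaves[i]] <- sprintf("%s.g%d", s, counts[s])
  }
  locus_map <- tibble::tibble(
    gene_id = g$label[leaves],
    species = spp,
    locus_id = sub("^([a-z]+)\\.g", "\\1_L", g$label[leaves]),
    isoform_id = "i1"
  )
  structure(list(
    gene_tree_true = g, sequences = NULL,
    true_dup_count = sum(g$event == "duplication", na.rm = TRUE),
    true_loss_count = sum(events$type == "death"),
    locus_map = locus_map, events = events, empty = FALSE,
    params = list(birth_rate = birth_rate, death_rate = death_rate,
                  root_copies = root_copies, seed = seed),
    species_tree = sp
  ), class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  if (x$empty) {
    cat("<simulated_family: extinct (empty) family,",
        x$true_loss_count, "losses>\n")
  } else {
    cat(sprintf("<simulated_family: %d genes, %d duplications, %d losses>\n",
                nrow(x$locus_map), x$true_dup_count, x$true_loss_count))
  }
  invisible(x)
}

#' Replay a logged birth-death simulation
#'
#' Reconstructs duplication and loss counts purely from the event log of
#' [simulate_gene_family()], independently of the emitted pruned tree: a
#' logged duplication counts only when both its descendant lineages reach
#' a leaf; every logged death counts as a loss.
#'
#' @param events the `events` tibble of a `simulated_family`.
#' @return A list with `dup_count` and `loss_count`.
#' @export
replay_family_events <- function(events) {
  term <- events[events$type %in% c("leaf", "death"), ]
  fate <- new.env(parent = emptyenv())
  by_lineage <- split(seq_len(nrow(events)), events$lineage)
  surv <- function(lineage) {
    key <- as.character(lineage)
    if (!is.null(fate[[key]])) return(fate[[key]])
    rows <- events[by_lineage[[key]], ]
    out <- FALSE
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$type == "leaf") out <- TRUE
      if (r$type == "death") out <- FALSE
      if (r$type %in% c("birth", "speciation")) {
        out <- surv(r$child1) || surv(r$child2)
      }
    }
    fate[[key]] <- out
    out
  }
  dups <- events[events$type == "birth", ]
  dup_count <- 0L
  if (nrow(dups)) {
    dup_count <- sum(vapply(seq_len(nrow(dups)), function(i) {
      surv(dups$child1[i]) && surv(dups$child2[i])
    }, logical(1)))
  }
  list(dup_count = as.integer(dup_count),
       loss_count = as.integer(sum(events$type == "death")))
}

#' Evolve protein sequences along a gene tree
#'
#' Gap-free Markov simulation under an empirical amino-acid model
#' (default Le-Gascuel exchangeabilities), with optional discrete-Gamma
#' among-site rate heterogeneity. The root sequence is drawn from the
#' model's stationary frequencies and each branch applies the transition
#' matrix `expm(Q t)` for its length `t` (substitutions/site).
#'
#' @param tree a `gtree` with nonnegative branch lengths.
#' @param length sequence length in residues.
#' @param subs_model `"LG"` or `"Poisson"`.
#' @param seed integer seed.
#' @param gamma_alpha optional shape of discrete-Gamma(`gamma_categories`)
#'   site rates; `NULL` disables rate heterogeneity.
#' @param gamma_categories number of discrete rate categories.
#' @return Named character vector of protein sequences, one per leaf.
#' @export
evolve_sequences <- function(tree, length, subs_model = "LG", seed,
                             gamma_alpha = NULL, gamma_categories = 4L) {
  if (length < 1) stop_input("`length` must be >= 1")
  if (!subs_model %in% aa_models()) {
    abort(paste0("unknown substitution model '", subs_model,
                 "'; supported models: ", paste(aa_models(), collapse = ", ")),
          class = "genetrace_config_error")
  }
  if (any(tree$length[-tree$root] < 0, na.rm = TRUE)) {
    stop_input("branch lengths must be >= 0")
  }
  mod <- aa_model(subs_model)
  with_seed(seed, {
    rates <- if (is.null(gamma_alpha)) rep(1, length) else {
      rcat <- discrete_gamma_rates(gamma_alpha, gamma_categories)
      rcat[sample.int(gamma_categories, length, replace = TRUE)]
    }
    urates <- sort(unique(rates))
    states <- vector("list", gtree_n(tree))
    states[[tree$root]] <- sample.int(20L, length, replace = TRUE, prob = mod$pi)
    ord <- rev(gtree_postorder(tree))  # preorder
    for (v in ord) {
      if (v == tree$root) next
      t <- tree$length[v]
      if (is.na(t)) t <- 0
      par_states <- states[[tree$parent[v]]]
      if (t == 0) {
        states[[v]] <- par_states
        next
      }
      out <- integer(length)
      for (r in urates) {
        sel <- which(rates == r)
        P <- aa_pmatrix(mod, t * r)
        for (s in unique(par_states[sel])) {
          at <- sel[par_states[sel] == s]
          out[at] <- sample.int(20L, base::length(at), replace = TRUE, prob = P[s, ])
        }
      }
      states[[v]] <- out
    }
    leaves <- gtree_leaves(tree)
    setNames(
      vapply(leaves, function(v) paste(.aa_alphabet[states[[v]]], collapse = ""), ""),
      tree$label[leaves]
    )
  })
}
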