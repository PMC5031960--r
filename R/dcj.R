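# Double-cut-and-join comparison of signed gene orders.
#
# Both genomes are reduced to partner vectors over the shared extremity
# universe; the adjacency graph's cycles (C) and odd paths (I) give the
# distance d = N - (C + I/2) (Bergeron-Mixtacki-Stoye form).

check_same_content <- function(a, b) {
  ua <- genome_genes(a); ub <- genome_genes(b)
  if (!identical(ua, ub)) {
    only_a <- setdiff(ua, ub); only_b <- setdiff(ub, ua)
    stop_input("genomes differ in gene content; only in ", a$name, ": {",
               paste(only_a, collapse = ","), "}, only in ", b$name, ": {",
               paste(only_b, collapse = ","), "}")
  }
  ua
}

# Cycle/odd-path counts for two partner vectors on the same universe.
# Components of the graph on extremities with edges e-pa[e] and e-pb[e]:
# a component is a cycle when no member is a telomere in either genome;
# otherwise it is a path whose adjacency-graph edge count equals the
# number of extremities in the component.
count_components <- function(pa, pb) {
  n2 <- length(pa)
  visited <- logical(n2)
  C <- 0L; I <- 0L
  for (s in seq_len(n2)) {
    if (visited[s]) next
    comp <- integer(0)
    stack <- s
    is_cycle <- TRUE
    while (length(stack)) {
      e <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[e]) next
      visited[e] <- TRUE
      comp <- c(comp, e)
      if (pa[e] == 0L || pb[e] == 0L) is_cycle <- FALSE
      if (pa[e] > 0L && !visited[pa[e]]) stack <- c(stack, pa[e])
      if (pb[e] > 0L && !visited[pb[e]]) stack <- c(stack, pb[e])
    }
    if (is_cycle) C <- C + 1L
    else if (length(comp) %% 2L == 1L) I <- I + 1L
  }
  list(C = C, I = I)
}

dist_partner <- function(pa, pb) {
  cc <- count_components(pa, pb)
  as.integer(length(pa) / 2L - cc$C - cc$I / 2L)
}

#' Adjacency graph of two genomes
#'
#' Builds the comparison structure between two genomes with identical
#' gene content: `N` shared genes, `C` cycles and `I` odd paths, giving
#' the DCJ distance `d = N - (C + I/2)`.
#'
#' @param a,b `genome` objects with identical unsigned gene content.
#' @return An object of class `adjacency_graph` with fields `N`, `C`,
#'   `I`, `d`.
#' @examples
#' g1 <- genome("a", list(c(1, 2, 3)))
#' g2 <- genome("b", list(c(1, -2, 3)))
#' build_adjacency_graph(g1, g2)$d
#' @export
build_adjacency_graph <- function(a, b) {
  universe <- check_same_content(a, b)
  pa <- genome_partner(a, universe)
  pb <- genome_partner(b, universe)
  cc <- count_components(pa, pb)
  structure(list(
    N = length(universe), C = cc$C, I = cc$I,
    d = as.integer(length(universe) - cc$C - cc$I / 2L),
    universe = universe, pa = pa, pb = pb
  ), class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph: N=%d, C=%d cycles, I=%d odd paths, d=%d>\n",
              x$N, x$C, x$I, x$d))
  invisible(x)
}

#' DCJ distance between two genomes
#'
#' The minimum number of double-cut-and-join operations transforming one
#' signed gene order into the other.
#'
#' @inheritParams build_adjacency_graph
#' @return A nonnegative integer.
#' @export
dcj_distance <- function(a, b) build_adjacency_graph(a, b)$d

#' A shortest DCJ sorting scenario
#'
#' Greedy optimal sorting: every target adjacency is installed by one DCJ
#' (when not already present), then excess adjacencies at target telomeres
#' are split. The returned scenario has length exactly
#' `dcj_distance(a, b)` and transforms `a` into `b`.
#'
#' @inheritParams build_adjacency_graph
#' @return An object of class `dcj_scenario`: list with `ops` (matrix of
#'   replacement extremity pairs), `universe`, `from`, `to`.
#' @export
dcj_sort <- function(a, b) {
  universe <- check_same_content(a, b)
  pa <- genome_partner(a, universe)
  pb <- genome_partner(b, universe)
  ops <- list()
  do_op <- function(op) {
    pa <<- apply_op(pa, op)
    ops[[length(ops) + 1L]] <<- op
  }
  adj_b <- which(pb > seq_along(pb))
  for (e in adj_b) {
    f <- pb[e]
    if (pa[e] == f) next
    x <- pa[e]; y <- pa[f]
    do_op(c(e, f, x, y))   # x and/or y may be 0 (telomeres)
  }
  telo_b <- which(pb == 0L)
  for (e in telo_b) {
    if (pa[e] > 0L) do_op(c(e, 0L, pa[e], 0L))
  }
  stopifnot(identical(pa, pb))
  structure(list(
    ops = if (length(ops)) do.call(rbind, ops) else matrix(0L, 0, 4),
    universe = universe, from = a$name, to = b$name
  ), class = "dcj_scenario")
}

#' @export
print.dcj_scenario <- function(x, ...) {
  cat(sprintf("<dcj_scenario: %s -> %s, %d operation(s)>\n",
              x$from, x$to, nrow(x$ops)))
  invisible(x)
}

#' Apply (a prefix of) a DCJ scenario to a genome
#'
#' @param g a `genome`.
#' @param scenario a `dcj_scenario` from [dcj_sort()].
#' @param k number of leading operations to apply (default: all).
#' @return The transformed `genome`.
#' @export
apply_dcj <- function(g, scenario, k = nrow(scenario$ops)) {
  p <- genome_partner(g, scenario$universe)
  for (i in seq_len(k)) p <- apply_op(p, scenario$ops[i, ])
  partner_genome(p, scenario$universe, name = g$name)
}

# --- median --------------------------------------------------------------

median_lower_bound <- function(pa, pb, pc) {
  ceiling((dist_partner(pa, pb) + dist_partner(pa, pc) + dist_partner(pb, pc)) / 2)
}

#' DCJ median of three genomes
#'
#' Finds a genome `m` minimizing `d(m,a) + d(m,b) + d(m,c)` — the
#' parsimony ancestor of three gene orders. `mode = "exact"` searches the
#' full space of genomes on the shared gene set (all pairings of
#' extremities into adjacencies and telomeres) with early termination at
#' the pairwise lower bound `ceiling((d(a,b)+d(a,c)+d(b,c))/2)`; it is
#' restricted to small instances. `mode = "heuristic"` steepest-descent
#' hill-climbs from each input genome over single-DCJ neighbours.
#'
#' @param a,b,c `genome` objects with identical gene content.
#' @param mode `"exact"` (gene count <= `exact_cap`) or `"heuristic"`.
#' @param exact_cap largest gene count accepted in exact mode.
#' @return A list with `median` (a `genome`), `score`, `lower_bound` and
#'   `mode`.
#' @export
dcj_median <- function(a, b, c, mode = c("exact", "heuristic"), exact_cap = 6L) {
  mode <- match.arg(mode)
  universe <- check_same_content(a, b)
  check_same_content(a, c)
  pa <- genome_partner(a, universe)
  pb <- genome_partner(b, universe)
  pc <- genome_partner(c, universe)
  lb <- median_lower_bound(pa, pb, pc)
  score_of <- function(p) {
    dist_partner(p, pa) + dist_partner(p, pb) + dist_partner(p, pc)
  }
  if (mode == "exact") {
    if (length(universe) > exact_cap) {
      stop_capability("exact DCJ median is limited to ", exact_cap,
                      " genes (got ", length(universe),
                      "); use mode = \"heuristic\"")
    }
    n2 <- length(pa)
    best_p <- pa
    best <- score_of(pa)
    p <- integer(n2)
    assigned <- logical(n2)
    rec <- function() {
      if (best <= lb) return()
      e <- which(!assigned)[1]
      if (is.na(e)) {
        s <- score_of(p)
        if (s < best) {
          best <<- s
          best_p <<- p
        }
        return()
      }
      assigned[e] <<- TRUE
      # e as a telomere
      p[e] <<- 0L
      rec()
      # e adjacent to each later unassigned extremity
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
    m <- partner_genome(best_p, universe, name = "median")
    return(list(median = m, score = best, lower_bound = lb, mode = "exact"))
  }
  # heuristic: steepest descent from each input genome
  best_p <- pa; best <- score_of(pa)
  for (start in list(pa, pb, pc)) {
    p <- start
    s <- score_of(p)
    repeat {
      improved <- FALSE
      for (op in all_dcj_ops(p)) {
        q <- apply_op(p, op)
        sq <- score_of(q)
        if (sq < s) {
          p <- q; s <- sq; improved <- TRUE
        }
      }
      if (!improved || s <= lb) break
    }
    if (s < best) {
      best <- s; best_p <- p
    }
  }
  list(median = partner_genome(best_p, universe, name = "median"),
       score = best, lower_bound = lb, mode = "heuristic")
}

#' Infer the ancestor of three genomes by the DCJ median
#'
#' Treats the three genomes as the leaves of a star tree, takes the DCJ
#' median as the ancestral gene order, and reports the rearrangement
#' count along each branch.
#'
#' @param genomes a named list of exactly three `genome` objects.
#' @param mode passed to [dcj_median()] (`"exact"` or `"heuristic"`).
#' @param exact_cap passed to [dcj_median()].
#' @return A list with `ancestor` (the median `genome`), `branch_counts`
#'   (tibble: leaf, operations), `score` and `lower_bound`.
#' @export
infer_ancestor <- function(genomes, mode = "heuristic", exact_cap = 6L) {
  if (length(genomes) != 3) stop_input("ancestor inference needs exactly 3 genomes")
  med <- dcj_median(genomes[[1]], genomes[[2]], genomes[[3]],
                    mode = mode, exact_cap = exact_cap)
  counts <- tibble::tibble(
    leaf = vapply(genomes, `[[`, "", "name"),
    operations = vapply(genomes, function(g) dcj_distance(med$median, g), 0L)
  )
  list(ancestor = med$median, branch_counts = counts,
       score = med$score, lower_bound = med$lower_bound)
}
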