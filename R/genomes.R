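#' Signed gene-order genomes
#'
#' A `genome` is an ordered set of chromosomes, each a sequence of signed
#' gene identifiers (sign = strand) that is either linear or circular.
#' Analyses operate on the ortholog-filtered single-copy set, so each
#' unsigned gene identifier must appear exactly once per genome.
#'
#' @param name genome name.
#' @param chromosomes a list; each element either a signed integer vector
#'   (taken as linear) or a list with `genes` (signed integers) and
#'   `circular` (logical).
#' @return An object of class `genome`.
#' @examples
#' g <- genome("anc", list(c(1, 2, 3)))
#' genome_genes(g)
#' @export
genome <- function(name, chromosomes) {
  chrs <- lapply(chromosomes, function(ch) {
    if (is.list(ch)) list(genes = as.integer(ch$genes), circular = isTRUE(ch$circular))
    else list(genes = as.integer(ch), circular = FALSE)
  })
  genes <- abs(unlist(lapply(chrs, `[[`, "genes")))
  if (length(genes) == 0) stop_input("genome must contain at least one gene")
  if (anyDuplicated(genes)) {
    stop_input("duplicated gene identifiers: ",
               paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (any(genes == 0)) stop_input("gene identifiers must be nonzero")
  structure(list(name = as.character(name), chromosomes = chrs), class = "genome")
}

#' @rdname genome
#' @param g a `genome`.
#' @export
genome_genes <- function(g) sort(abs(unlist(lapply(g$chromosomes, `[[`, "genes"))))

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome %s: %d genes, %d chromosome(s)>\n",
              x$name, length(genome_genes(x)), length(x$chromosomes)))
  for (ch in x$chromosomes) {
    cat(" ", paste(ifelse(ch$genes > 0, paste0("+", ch$genes), ch$genes),
                   collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  }
  invisible(x)
}

# --- extremity / partner-vector representation ---------------------------
# Gene i (position in the sorted gene universe) has tail 2i-1 and head 2i.
# A genome is a perfect "partial matching" on extremities: partner[e] is
# the extremity adjacent to e, or 0 when e is a telomere.

ext_of <- function(signed_pos) {
  # left and right extremity of a signed gene given its universe position
  i <- as.integer(abs(signed_pos))
  if (signed_pos > 0) c(2L * i - 1L, 2L * i) else c(2L * i, 2L * i - 1L)
}

genome_partner <- function(g, universe = genome_genes(g)) {
  n <- length(universe)
  p <- integer(2L * n)
  for (ch in g$chromosomes) {
    pos <- match(abs(ch$genes), universe)
    if (anyNA(pos)) stop_input("genome contains genes outside the universe")
    signed <- sign(ch$genes) * pos
    k <- length(signed)
    ends <- t(vapply(signed, ext_of, integer(2)))  # cols: left, right
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        a <- ends[j, 2]; b <- ends[j + 1, 1]
        p[a] <- b; p[b] <- a
      }
    }
    if (ch$circular) {
      a <- ends[k, 2]; b <- ends[1, 1]
      if (a == b) stop_input("invalid circular single-extremity chromosome")
      p[a] <- b; p[b] <- a
    }
  }
  p
}

partner_genome <- function(p, universe, name = "genome") {
  n <- length(universe)
  used <- logical(2L * n)
  chrs <- list()
  walk <- function(start) {
    # start is a left extremity of its first gene
    genes <- integer(0)
    e <- start
    repeat {
      used[e] <<- TRUE
      i <- (e + 1L) %/% 2L
      signed <- if (e %% 2L == 1L) i else -i
      genes <- c(genes, sign(signed) * universe[abs(signed)])
      r <- if (e %% 2L == 1L) e + 1L else e - 1L  # right extremity
      used[r] <<- TRUE
      nxt <- p[r]
      if (nxt == 0L) return(list(genes = genes, circular = FALSE))
      if (used[nxt]) return(list(genes = genes, circular = TRUE))
      e <- nxt
    }
  }
  # linear chromosomes: start at each unused telomere
  telos <- which(p == 0L)
  for (e in telos) {
    if (!used[e]) chrs[[length(chrs) + 1L]] <- walk(e)
  }
  # circular chromosomes from remaining extremities
  for (e in seq_len(2L * n)) {
    if (!used[e]) chrs[[length(chrs) + 1L]] <- walk(e)
  }
  genome(name, chrs)
}

# Canonical key of a partner vector (for genome identity / BFS search).
partner_key <- function(p) paste(p, collapse = ",")

genome_equal <- function(a, b) {
  ua <- genome_genes(a); ub <- genome_genes(b)
  identical(ua, ub) && identical(genome_partner(a, ua), genome_partner(b, ua))
}

# --- DCJ operations on partner vectors ----------------------------------
# An operation is encoded as c(e1, e2, e3, e4): the replacement pairs
# {e1,e2} and {e3,e4}; a 0 in the second slot of a pair means the first
# slot becomes a telomere; a pair of zeros is absent.

apply_op <- function(p, op) {
  set <- function(x, y) {
    if (x > 0L) p[x] <<- y
    if (y > 0L) p[y] <<- x
  }
  set(op[1], op[2])
  set(op[3], op[4])
  p
}

# All distinct single-DCJ operations applicable to p.
all_dcj_ops <- function(p) {
  adj <- which(p > seq_along(p))            # e with partner f > e
  adjs <- cbind(adj, p[adj])                # rows {a, b}
  telo <- which(p == 0L)
  ops <- list()
  na <- nrow(adjs); nt <- length(telo)
  if (na >= 2) {
    for (i in 1:(na - 1)) for (j in (i + 1):na) {
      a <- adjs[i, 1]; b <- adjs[i, 2]; c <- adjs[j, 1]; d <- adjs[j, 2]
      ops[[length(ops) + 1L]] <- c(a, c, b, d)
      ops[[length(ops) + 1L]] <- c(a, d, b, c)
    }
  }
  if (na >= 1 && nt >= 1) {
    for (i in seq_len(na)) for (tt in telo) {
      a <- adjs[i, 1]; b <- adjs[i, 2]
      ops[[length(ops) + 1L]] <- c(a, tt, b, 0L)
      ops[[length(ops) + 1L]] <- c(b, tt, a, 0L)
    }
  }
  if (nt >= 2) {
    for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
      ops[[length(ops) + 1L]] <- c(telo[i], telo[j], 0L, 0L)
    }
  }
  if (na >= 1) {
    for (i in seq_len(na)) {
      ops[[length(ops) + 1L]] <- c(adjs[i, 1], 0L, adjs[i, 2], 0L)
    }
  }
  ops
}

#' Simulate genome divergence by random DCJ operations
#'
#' Starting from `ancestor` at the species-tree root, each branch applies
#' exactly `ops_per_branch` double-cut-and-join operations drawn uniformly
#' from all valid operations on the current genome (inversions, fissions,
#' fusions, translocations, circularizations). Gene content is preserved
#' by construction; the operation log is retained per branch.
#'
#' @param ancestor a `genome`.
#' @param tree a species `gtree` (default [species_tree_default()]).
#' @param ops_per_branch nonnegative integer, recycled over branches.
#' @param seed integer seed.
#' @return An object of class `simulated_genomes`: list with `ancestor`,
#'   `leaves` (named list of `genome`), `internal` (genomes at internal
#'   species nodes), `ops_applied` (list of operation matrices per branch,
#'   named by the species clade below the branch) and `seed`.
#' @export
simulate_genome_evolution <- function(ancestor, tree = species_tree_default(),
                                      ops_per_branch = 2L, seed) {
  if (any(ops_per_branch < 0)) stop_input("ops_per_branch must be >= 0")
  universe <- genome_genes(ancestor)
  ck <- clade_keys(tree)
  branches <- which(tree$parent > 0L)
  k_branch <- rep(as.integer(ops_per_branch), length.out = length(branches))
  names(k_branch) <- as.character(branches)

  with_seed(seed, {
    states <- vector("list", gtree_n(tree))
    states[[tree$root]] <- genome_partner(ancestor, universe)
    ops_applied <- list()
    for (v in rev(gtree_postorder(tree))) {
      if (v == tree$root) next
      p <- states[[tree$parent[v]]]
      k <- k_branch[[as.character(v)]]
      oplog <- matrix(0L, nrow = k, ncol = 4)
      for (i in seq_len(k)) {
        ops <- all_dcj_ops(p)
        op <- ops[[sample.int(length(ops), 1L)]]
        p <- apply_op(p, op)
        oplog[i, ] <- op
      }
      states[[v]] <- p
      ops_applied[[gsub("\\|", "-", ck[v])]] <- oplog
    }
    leaves <- gtree_leaves(tree)
    leaf_genomes <- lapply(leaves, function(v) {
      partner_genome(states[[v]], universe, name = tree$label[v])
    })
    names(leaf_genomes) <- tree$label[leaves]
    internal <- lapply(setdiff(gtree_internal(tree), tree$root), function(v) {
      partner_genome(states[[v]], universe, name = gsub("\\|", "-", ck[v]))
    })
    structure(list(ancestor = ancestor, leaves = leaf_genomes,
                   internal = internal, ops_applied = ops_applied, seed = seed),
              class = "simulated_genomes")
  })
}

#' Generate a random single-copy genome
#'
#' @param n_genes number of genes (identifiers `1..n_genes`).
#' @param n_chromosomes number of chromosomes.
#' @param circular logical, recycled over chromosomes.
#' @param seed integer seed.
#' @param name genome name.
#' @return A `genome` with random gene order and orientations.
#' @export
random_genome <- function(n_genes, n_chromosomes = 1L, circular = FALSE, seed,
                          name = "random") {
  if (n_genes < n_chromosomes) stop_input("need at least one gene per chromosome")
  with_seed(seed, {
    perm <- sample.int(n_genes) * sample(c(-1L, 1L), n_genes, replace = TRUE)
    cuts <- sort(sample.int(n_genes - 1L, n_chromosomes - 1L))
    bounds <- c(0L, cuts, n_genes)
    circ <- rep(circular, length.out = n_chromosomes)
    chrs <- lapply(seq_len(n_chromosomes), function(i) {
      list(genes = perm[(bounds[i] + 1L):bounds[i + 1L]], circular = circ[i])
    })
    genome(name, chrs)
  })
}

# --- GRIMM-style text I/O ------------------------------------------------

#' Read and write GRIMM gene-order files
#'
#' GRIMM conventions: a `>name` header introduces each genome; chromosomes
#' are lines of signed integers terminated by `$` (linear) or `@`
#' (circular).
#'
#' @param path file path.
#' @return `read_grimm()`: a named list of `genome` objects.
#' @export
read_grimm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  cur_name <- NULL; cur_chrs <- list()
  flush <- function() {
    if (!is.null(cur_name)) out[[cur_name]] <<- genome(cur_name, cur_chrs)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(sub("^>", "", ln))
      cur_chrs <- list()
    } else {
      toks <- strsplit(ln, "\\s+")[[1]]
      circ <- identical(toks[length(toks)], "@")
      if (toks[length(toks)] %in% c("$", "@")) toks <- toks[-length(toks)]
      cur_chrs[[length(cur_chrs) + 1L]] <-
        list(genes = as.integer(toks), circular = circ)
    }
  }
  flush()
  out
}

#' @rdname read_grimm
#' @param genomes a `genome` or list of `genome` objects.
#' @export
write_grimm <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  lines <- unlist(lapply(genomes, function(g) {
    c(paste0(">", g$name),
      vapply(g$chromosomes, function(ch) {
        paste(c(ch$genes, if (ch$circular) "@" else "$"), collapse = " ")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
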