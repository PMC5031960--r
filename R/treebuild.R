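# Distance-based gene-tree construction: corrected protein distances,
# neighbor joining, and nonparametric bootstrap supports.

as_aln_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop_input("alignment sequences must have unique names")
  }
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop_input("aligned sequences must have equal length")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

# Cap applied to the observed proportion of differences before the
# Poisson correction, to keep distances finite for near-saturated pairs.
.pdist_cap <- 0.93

#' Corrected pairwise distances from a protein alignment
#'
#' Pairwise p-distances over columns without a gap in either sequence,
#' Poisson-corrected (`d = -log(1 - p)`). Near-saturated pairs
#' (`p >= 0.93`, including pairs with no shared ungapped columns) are
#' capped at the corrected value of the cap, with a warning.
#'
#' @param alignment named character vector or `AAStringSet` of aligned
#'   (gapped) protein sequences, at least 3.
#' @return A symmetric numeric matrix of distances
#'   (substitutions/site), zero diagonal.
#' @export
protein_distance_matrix <- function(alignment) {
  m <- as_aln_matrix(alignment)
  if (nrow(m) < 3) stop_input("need at least 3 sequences")
  n <- nrow(m)
  gap <- m == "-" | m == "." | m == "?"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- FALSE
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) {
      p <- .pdist_cap
      capped <- TRUE
    } else {
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= .pdist_cap) {
        p <- .pdist_cap
        capped <- TRUE
      }
    }
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  if (capped) {
    warn(sprintf("near-saturated pairs capped at p = %.2f (d = %.3f)",
                 .pdist_cap, -log(1 - .pdist_cap)))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero. The agglomeration order is
#' deterministic for a given matrix.
#'
#' @param d symmetric nonnegative distance matrix over at least 3 taxa.
#' @return An unrooted binary `gtree`.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_input("`d` must be a square matrix")
  if (nrow(d) < 3) stop_input("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop_input("`d` must be symmetric")
  if (any(d < 0)) stop_input("`d` must be nonnegative")
  phy <- ape::nj(as.dist(d))
  phy$edge.length[phy$edge.length < 0] <- 0
  gtree_from_phylo(phy)
}

# Internal split keys of an unrooted-representation gtree (edges above
# internal non-root nodes).
internal_splits <- function(g) {
  sk <- split_keys(g)
  nodes <- setdiff(gtree_internal(g), g$root)
  setNames(sk[nodes], as.character(nodes))
}

#' Nonparametric bootstrap supports for a gene tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree for each replicate, and scores each internal
#' bipartition of the point-estimate tree by the percentage of
#' replicates containing it.
#'
#' @param alignment named character vector or `AAStringSet` (gap-free or
#'   gapped), at least 2 columns.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param tree optional point-estimate `gtree`; by default the NJ tree
#'   of the full alignment.
#' @return The point-estimate `gtree` with supports (0-100) on internal
#'   branches.
#' @export
bootstrap_supports <- function(alignment, n_reps = 100L, seed, tree = NULL) {
  if (n_reps < 1) stop_input("n_reps must be >= 1")
  m <- as_aln_matrix(alignment)
  if (ncol(m) < 2) stop_input("alignment must have at least 2 columns")
  aln_from_matrix <- function(mm) {
    setNames(apply(mm, 1, paste, collapse = ""), rownames(mm))
  }
  if (is.null(tree)) {
    tree <- neighbor_joining(protein_distance_matrix(aln_from_matrix(m)))
  }
  if (length(tree$children[[tree$root]]) == 2) tree <- unroot_gtree(tree)
  target <- internal_splits(tree)
  hits <- setNames(numeric(length(target)), names(target))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- suppressWarnings(
        neighbor_joining(protein_distance_matrix(aln_from_matrix(m[, cols, drop = FALSE])))
      )
      rep_splits <- internal_splits(rep_tree)
      hits <- hits + as.numeric(target %in% rep_splits)
    }
  })
  for (nm in names(target)) {
    tree$support[as.integer(nm)] <- round(100 * hits[[nm]] / n_reps)
  }
  tree
}
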