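#' Lightweight rooted tree structure
#'
#' `gtree` is the package's internal tree representation: a flat,
#' index-addressed rooted tree that tolerates polytomies and carries, per
#' node, the branch length and bootstrap support of the edge *above* the
#' node plus an optional evolutionary event label
#' (`"duplication"`/`"speciation"`/`"loss"`). Conversions to and from
#' [ape::read.tree()]'s `phylo` give access to the ape/phangorn toolbox;
#' `gtree` itself makes reconciliation, rerooting and refinement
#' manipulations straightforward.
#'
#' @param parent integer vector; `parent[i]` is the parent index of node
#'   `i`, `0` for the root.
#' @param label character vector of node labels (leaves must be labelled).
#' @param length numeric vector of branch lengths above each node.
#' @param support numeric vector of supports (internal edges), `NA` elsewhere.
#' @param event optional character vector of event labels.
#' @return An object of class `gtree`.
#' @keywords internal
new_gtree <- function(parent, label = NULL, length = NULL, support = NULL,
                      event = NULL) {
  n <- base::length(parent)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  root <- which(parent == 0L)
  if (base::length(root) != 1L) stop_input("tree must have exactly one root")
  structure(list(
    parent = as.integer(parent),
    children = children,
    label = if (is.null(label)) character(n) else as.character(label),
    length = if (is.null(length)) rep(NA_real_, n) else as.numeric(length),
    support = if (is.null(support)) rep(NA_real_, n) else as.numeric(support),
    event = if (is.null(event)) rep(NA_character_, n) else as.character(event),
    root = as.integer(root)
  ), class = "gtree")
}

gtree_n <- function(g) length(g$parent)

#' Basic gtree accessors
#'
#' `gtree_leaves()`/`gtree_internal()` return node indices,
#' `is_binary_gtree()` tests whether every internal node has exactly two
#' children, and `topo_key()` gives a canonical parenthesized string of
#' the rooted topology (labels sorted; lengths and supports ignored),
#' usable as an identity key.
#'
#' @param g a `gtree`.
#' @return Integer node indices, a logical, or a character key.
#' @export
gtree_leaves <- function(g) which(lengths(g$children) == 0L)

#' @rdname gtree_leaves
#' @export
gtree_internal <- function(g) which(lengths(g$children) > 0L)

#' @rdname gtree_leaves
#' @export
is_binary_gtree <- function(g) all(lengths(g$children) %in% c(0L, 2L))

# Postorder node indices (children before parents).
gtree_postorder <- function(g) {
  n <- gtree_n(g)
  out <- integer(n)
  k <- 0L
  stack <- c(g$root)
  emit <- integer(n)  # reverse preorder = postorder reversed
  m <- 0L
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    m <- m + 1L
    emit[m] <- v
    ch <- g$children[[v]]
    if (length(ch)) stack <- c(stack, ch)
  }
  rev(emit[seq_len(m)])
}

# Species code of each leaf label ("spp.gene" convention).
species_code <- function(labels) sub("\\..*$", "", labels)

# --- recursive-list view -------------------------------------------------
# rlist node: list(label, length, support, event, children = list(...))

gtree_to_rlist <- function(g, node = g$root) {
  ch <- g$children[[node]]
  list(
    label = g$label[node], length = g$length[node],
    support = g$support[node], event = g$event[node],
    children = lapply(ch, function(c) gtree_to_rlist(g, c))
  )
}

rlist_node <- function(label = "", length = NA_real_, support = NA_real_,
                       event = NA_character_, children = list()) {
  list(label = label, length = length, support = support, event = event,
       children = children)
}

rlist_to_gtree <- function(r) {
  parent <- integer(0); label <- character(0); len <- numeric(0)
  sup <- numeric(0); ev <- character(0)
  add <- function(node, p) {
    parent[length(parent) + 1L] <<- p
    i <- length(parent)
    label[i] <<- node$label %||% ""
    len[i] <<- node$length %||% NA_real_
    sup[i] <<- node$support %||% NA_real_
    ev[i] <<- node$event %||% NA_character_
    for (c in node$children) add(c, i)
    i
  }
  add(r, 0L)
  new_gtree(parent, label, len, sup, ev)
}

# --- phylo conversion ----------------------------------------------------

#' Convert between gtree and ape's phylo
#'
#' @param phy a `phylo` object.
#' @return `gtree_from_phylo()`: a `gtree`; `gtree_to_phylo()`: a `phylo`.
#' @export
gtree_from_phylo <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  label <- character(nn)
  label[seq_len(nt)] <- phy$tip.label
  len <- rep(NA_real_, nn)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  sup <- rep(NA_real_, nn)
  if (!is.null(phy$node.label)) {
    s <- suppressWarnings(as.numeric(phy$node.label))
    sup[nt + seq_len(phy$Nnode)] <- s
  }
  g <- new_gtree(parent, label, len, sup)
  g$support[g$root] <- NA_real_
  g
}

#' @rdname gtree_from_phylo
#' @param g a `gtree`.
#' @export
gtree_to_phylo <- function(g) {
  leaves <- gtree_leaves(g)
  internal <- gtree_internal(g)
  nt <- length(leaves)
  id <- integer(gtree_n(g))
  id[leaves] <- seq_len(nt)
  # root must be the first internal node in phylo numbering
  internal <- c(g$root, setdiff(internal, g$root))
  id[internal] <- nt + seq_along(internal)
  edges <- which(g$parent > 0L)
  edge <- cbind(id[g$parent[edges]], id[edges])
  phy <- list(
    edge = edge,
    tip.label = g$label[leaves],
    Nnode = length(internal),
    edge.length = if (all(is.na(g$length[edges]))) NULL else {
      el <- g$length[edges]; el[is.na(el)] <- 0; el
    },
    node.label = {
      nl <- g$support[internal]
      ifelse(is.na(nl), "", format(nl, trim = TRUE))
    }
  )
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

# --- newick / NHX --------------------------------------------------------

format_len <- function(x) {
  if (is.na(x)) "" else paste0(":", format(x, digits = 10, scientific = FALSE, trim = TRUE))
}

#' Write a gene tree as Newick/NHX text
#'
#' Internal node comments carry the reconciliation event
#' (`[&&NHX:D=Y]` for duplications, `D=N` for speciations) when event
#' labels are present; bootstrap supports become internal node labels.
#'
#' @param g a `gtree`.
#' @param nhx emit NHX event tags?
#' @return A single Newick string (with trailing `;`).
#' @export
gtree_newick <- function(g, nhx = FALSE) {
  rec <- function(v) {
    ch <- g$children[[v]]
    tag <- ""
    if (nhx && !is.na(g$event[v]) && g$event[v] %in% c("duplication", "speciation")) {
      tag <- sprintf("[&&NHX:D=%s]", if (g$event[v] == "duplication") "Y" else "N")
    }
    if (length(ch) == 0) {
      paste0(g$label[v], format_len(g$length[v]), tag)
    } else {
      lab <- if (!is.na(g$support[v])) format(g$support[v], trim = TRUE) else g$label[v]
      paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")",
             lab, format_len(g$length[v]), tag)
    }
  }
  paste0(rec(g$root), ";")
}

#' Read a Newick string into the package's tree structure
#'
#' Numeric internal node labels are interpreted as bootstrap supports.
#'
#' @param text a Newick string.
#' @return A `gtree`.
#' @export
read_gtree <- function(text) {
  gtree_from_phylo(ape::read.tree(text = text))
}

#' @export
print.gtree <- function(x, ...) {
  nl <- length(gtree_leaves(x))
  cat(sprintf("<gtree: %d leaves, %d nodes%s>\n", nl, gtree_n(x),
              if (is_binary_gtree(x)) ", binary" else ""))
  cat(gtree_newick(x, nhx = any(!is.na(x$event))), "\n")
  invisible(x)
}

# --- topology keys and clades -------------------------------------------

#' @rdname gtree_leaves
#' @param node subtree root (default: the tree root).
#' @export
topo_key <- function(g, node = g$root) {
  rec <- function(v) {
    ch <- g$children[[v]]
    if (length(ch) == 0) return(g$label[v])
    paste0("(", paste(sort(vapply(ch, rec, "")), collapse = ","), ")")
  }
  rec(node)
}

# Leaf-label sets per node, as sorted keys; names are node indices.
clade_keys <- function(g) {
  n <- gtree_n(g)
  sets <- vector("list", n)
  for (v in gtree_postorder(g)) {
    ch <- g$children[[v]]
    sets[[v]] <- if (length(ch) == 0) g$label[v] else
      sort(unlist(sets[ch], use.names = FALSE))
  }
  vapply(sets, paste, "", collapse = "|")
}

# Unrooted split key for an edge above node v: the side of the bipartition
# NOT containing the reference leaf, so keys agree across rootings.
split_keys <- function(g) {
  all_leaves <- sort(g$label[gtree_leaves(g)])
  ref <- all_leaves[1]
  ck <- clade_keys(g)
  sapply(seq_len(gtree_n(g)), function(v) {
    below <- strsplit(ck[v], "|", fixed = TRUE)[[1]]
    side <- if (ref %in% below) setdiff(all_leaves, below) else below
    paste(sort(side), collapse = "|")
  })
}

# --- rerooting -----------------------------------------------------------

# Splice out a 2-child root: returns a tree whose root is an internal node
# of the unrooted topology (standard unrooted representation).
unroot_gtree <- function(g) {
  r <- g$root
  ch <- g$children[[r]]
  if (length(ch) != 2) return(g)
  rl <- gtree_to_rlist(g)
  a <- rl$children[[1]]; b <- rl$children[[2]]
  # hang b below a (a becomes the new root); merged edge gets summed length
  into <- if (length(a$children) > 0) list(host = a, guest = b) else list(host = b, guest = a)
  host <- into$host; guest <- into$guest
  if (length(host$children) == 0) stop_input("cannot unroot a 2-leaf tree")
  guest$length <- sum(c(a$length, b$length), na.rm = TRUE)
  guest$support <- max(c(a$support, b$support), na.rm = TRUE)
  if (!is.finite(guest$support)) guest$support <- NA_real_
  host$children <- c(host$children, list(guest))
  host$length <- NA_real_; host$support <- NA_real_
  rlist_to_gtree(host)
}

# Orient the tree from `node`, arriving from neighbor `from` (0 = none).
# Edge values between x and its neighbor y belong to whichever of x,y is
# the child in the stored orientation.
orient_rlist <- function(g, node, from, edge_len, edge_sup) {
  nb <- c(if (g$parent[node] > 0) g$parent[node] else integer(0), g$children[[node]])
  nb <- setdiff(nb, from)
  kids <- lapply(nb, function(w) {
    if (g$parent[w] == node) {
      orient_rlist(g, w, node, g$length[w], g$support[w])
    } else {
      # w is the stored parent of node: edge values live on `node`
      orient_rlist(g, w, node, g$length[node], g$support[node])
    }
  })
  rlist_node(label = if (length(nb) == 0) g$label[node] else "",
             length = edge_len, support = edge_sup, children = kids)
}

# Root the (unrooted-representation) tree on the edge above node v.
root_on_edge <- function(g, v) {
  u <- g$parent[v]
  if (u == 0) stop_input("cannot root on the root pseudo-edge")
  half <- if (is.na(g$length[v])) NA_real_ else g$length[v] / 2
  a <- orient_rlist(g, v, u, half, g$support[v])
  b <- orient_rlist(g, u, v, half, g$support[v])
  rlist_to_gtree(rlist_node(children = list(a, b)))
}

#' Enumerate all rootings of an unrooted gene tree
#'
#' One rooted tree per branch of the unrooted topology; rooting on every
#' branch subsumes rooting at every node for reconciliation purposes.
#'
#' @param g a `gtree` in unrooted representation (basal multifurcation), or
#'   a rooted tree (which is unrooted first).
#' @return A list of rooted `gtree` objects.
#' @export
enumerate_rootings <- function(g) {
  if (length(gtree_leaves(g)) < 3) stop_input("need at least 3 leaves to enumerate rootings")
  if (length(g$children[[g$root]]) == 2) g <- unroot_gtree(g)
  lapply(which(g$parent > 0L), function(v) root_on_edge(g, v))
}

#' Collapse weakly supported branches
#'
#' Internal branches whose bootstrap support falls below `threshold` are
#' contracted, turning the tree into a (generally non-binary) unrooted
#' tree. Leaf branches are never contracted; branches without a support
#' value are kept.
#'
#' @param g a `gtree` with supports on internal branches.
#' @param threshold numeric support threshold; branches with
#'   `support < threshold` are removed.
#' @return An unrooted-representation `gtree`.
#' @export
contract_low_support <- function(g, threshold) {
  if (length(g$children[[g$root]]) == 2) g <- unroot_gtree(g)
  rl <- gtree_to_rlist(g)
  contract <- function(node) {
    if (length(node$children) == 0) return(node)
    kids <- lapply(node$children, contract)
    out <- list()
    for (k in kids) {
      drop_edge <- length(k$children) > 0 && !is.na(k$support) &&
        k$support < threshold
      if (drop_edge) out <- c(out, k$children) else out <- c(out, list(k))
    }
    node$children <- out
    node
  }
  rlist_to_gtree(contract(rl))
}
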