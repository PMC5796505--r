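#' Unrooted binary phylogenetic trees
#'
#' `parsboot` stores topologies as an adjacency table: nodes `1..(2n-2)`,
#' tips `1..n` (tip `i` carries `tip_label[i]`), internal nodes of degree 3.
#' Slot value 0 marks an unused neighbour slot.  Parsimony trees are purely
#' topological; no branch lengths are kept.
#'
#' @param nb integer matrix `(2n-2) x 3` of neighbour ids (0 = empty).
#' @param tip_label character vector of taxon labels (length `n`).
#' @return An object of class `mptree`.
#' @export
mptree <- function(nb, tip_label) {
  t <- structure(list(nb = nb, ntip = length(tip_label),
                      tip_label = as.character(tip_label)),
                 class = "mptree")
  validate_mptree(t)
  t
}

#' Validate the structural invariants of an `mptree`
#'
#' Checks binary degrees, connectivity and acyclicity; errors on violation.
#'
#' @param t an `mptree`.
#' @return `t`, invisibly.
#' @export
validate_mptree <- function(t) {
  n <- t$ntip
  nb <- t$nb
  if (n < 4L) stop("an unrooted binary tree needs at least 4 tips")
  if (anyDuplicated(t$tip_label)) stop("duplicate tip labels")
  if (!is.matrix(nb) || nrow(nb) != 2L * n - 2L || ncol(nb) != 3L)
    stop("nb must be a (2n-2) x 3 integer matrix")
  deg <- rowSums(nb > 0L)
  if (any(deg[seq_len(n)] != 1L)) stop("every tip must have degree 1")
  if (any(deg[(n + 1L):(2L * n - 2L)] != 3L))
    stop("every internal node must have degree 3")
  # symmetry of adjacency
  for (v in seq_len(nrow(nb))) {
    for (u in nb[v, ]) {
      if (u > 0L && !any(nb[u, ] == v)) stop("adjacency table not symmetric")
    }
  }
  # connected with nnode-1 edges => tree
  if (sum(deg) != 2L * (nrow(nb) - 1L)) stop("edge count wrong for a tree")
  seen <- logical(nrow(nb))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (u in nb[v, ]) {
      if (u > 0L && !seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
  }
  if (!all(seen)) stop("tree is not connected")
  invisible(t)
}

#' @export
print.mptree <- function(x, ...) {
  cat("Unrooted parsimony tree with", x$ntip, "tips\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

# parent vector and children-before-parent order, rooted at node `root`
tree_orders <- function(t, root = 1L) {
  nb <- t$nb
  parent <- rep(-1L, nrow(nb))
  parent[root] <- 0L
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (u in nb[v, ]) {
      if (u > 0L && u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
    }
  }
  list(parent = parent, postorder = rev(pre))
}

#' Nontrivial splits of a tree
#'
#' Each internal edge bipartitions the taxa; a split is encoded as the sorted
#' tip-index set on the side not containing tip 1, pasted into a key string.
#' An unrooted binary tree on `n` tips has exactly `n - 3` such splits.
#'
#' @param t an `mptree`.
#' @return character vector of split keys.
#' @export
split_keys <- function(t) {
  n <- t$ntip
  ord <- tree_orders(t, root = 1L)
  post <- ord$postorder
  parent <- ord$parent
  clades <- vector("list", nrow(t$nb))
  keys <- character(0)
  for (v in post) {
    if (v <= n) {
      clades[[v]] <- v
    } else {
      kids <- t$nb[v, ][t$nb[v, ] > 0L & t$nb[v, ] != parent[v]]
      cl <- sort(unlist(clades[kids]))
      clades[[v]] <- cl
      # the internal node adjacent to tip 1 spans all other tips: trivial
      if (length(cl) >= 2L && length(cl) <= n - 2L)
        keys <- c(keys, paste(cl, collapse = ","))
    }
  }
  keys
}

#' Topological identity of two trees
#'
#' Trees over the same taxa are equal iff their nontrivial split sets are
#' equal.  Tip labels are matched by name, not position.
#'
#' @param a,b `mptree` objects.
#' @return logical.
#' @export
tree_equal <- function(a, b) {
  if (!setequal(a$tip_label, b$tip_label)) return(FALSE)
  b2 <- remap_tips(b, a$tip_label)
  setequal(split_keys(a), split_keys(b2))
}

# re-index tips of `t` so that tip i carries taxa[i]
remap_tips <- function(t, taxa) {
  perm <- match(t$tip_label, taxa)
  if (anyNA(perm)) stop("taxa sets differ")
  n <- t$ntip
  map <- seq_len(nrow(t$nb))
  map[seq_len(n)] <- perm
  nb <- t$nb
  pos <- nb > 0L
  nb[pos] <- map[nb[pos]]
  nb[seq_len(n), ] <- nb[order(perm), , drop = FALSE][, , drop = FALSE]
  mptree(nb, taxa)
}

#' Parse a Newick string into an `mptree`
#'
#' Accepts rooted or unrooted binary Newick (branch lengths and internal
#' labels are ignored); a bifurcating root is suppressed.  Polytomies are
#' rejected: consensus trees with polytomies live as `ape::phylo` objects.
#'
#' @param text a Newick string.
#' @param taxa optional taxon ordering; if given, the tree's tips must be
#'   exactly this set and tip indices follow it.
#' @return an `mptree`.
#' @export
parse_newick <- function(text, taxa = NULL) {
  text <- trimws(text)
  nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (nopen != nclose || !grepl(";\\s*$", text))
    stop("newick parse error: unbalanced parentheses or missing ';'")
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph)) stop("newick parse error")
  phylo_to_mptree(ph, taxa = taxa)
}

#' Convert an `ape::phylo` tree to an `mptree`
#'
#' @param ph a binary `phylo` tree (rooted trees are unrooted first).
#' @param taxa optional taxon ordering (see [parse_newick()]).
#' @return an `mptree`.
#' @export
phylo_to_mptree <- function(ph, taxa = NULL) {
  if (ape::is.rooted(ph)) ph <- ape::unroot(ph)
  n <- length(ph$tip.label)
  if (n < 4L) stop("need at least 4 taxa")
  if (ph$Nnode != n - 2L)
    stop("tree is not an unrooted binary tree (polytomy?)")
  if (is.null(taxa)) taxa <- ph$tip.label
  if (!setequal(taxa, ph$tip.label) || length(taxa) != n)
    stop("unknown taxa in newick tree")
  tipmap <- match(ph$tip.label, taxa)
  nb <- matrix(0L, 2L * n - 2L, 3L)
  add_edge <- function(nb, a, b) {
    nb[a, which(nb[a, ] == 0L)[1L]] <- b
    nb[b, which(nb[b, ] == 0L)[1L]] <- a
    nb
  }
  for (e in seq_len(nrow(ph$edge))) {
    a <- ph$edge[e, 1L]
    b <- ph$edge[e, 2L]
    a2 <- if (a <= n) tipmap[a] else a
    b2 <- if (b <= n) tipmap[b] else b
    nb <- add_edge(nb, a2, b2)
  }
  mptree(nb, taxa)
}

#' Write an `mptree` as a Newick string
#'
#' The tree is written rooted at the internal node adjacent to tip 1
#' (basal trifurcation, the standard rendering of an unrooted tree).
#'
#' @param t an `mptree`.
#' @param support optional named numeric vector of per-split supports
#'   (names are [split_keys()] keys); written as internal node labels,
#'   rounded half-up to integers.
#' @return a Newick string.
#' @export
write_newick <- function(t, support = NULL) {
  n <- t$ntip
  root <- t$nb[1L, 1L]
  ord <- tree_orders(t, root = root)
  parent <- ord$parent
  lab <- function(cl) {
    if (is.null(support)) return("")
    key <- paste(sort(cl), collapse = ",")
    if (!key %in% names(support)) return("")
    sprintf("%d", floor(support[[key]] + 0.5))
  }
  rec <- function(v) {
    if (v <= n) return(list(str = t$tip_label[v], clade = v))
    kids <- t$nb[v, ][t$nb[v, ] > 0L & t$nb[v, ] != parent[v]]
    parts <- lapply(kids, rec)
    cl <- sort(unlist(lapply(parts, `[[`, "clade")))
    str <- paste0("(", paste(vapply(parts, `[[`, "", "str"),
                             collapse = ","), ")")
    if (length(cl) >= 2L && length(cl) <= n - 2L && !1L %in% cl)
      str <- paste0(str, lab(cl))
    list(str = str, clade = cl)
  }
  kids <- t$nb[root, ]
  parts <- lapply(kids, rec)
  paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","), ");")
}

#' Convert an `mptree` to `ape::phylo`
#'
#' @inheritParams write_newick
#' @return a `phylo` object.
#' @export
mptree_to_phylo <- function(t, support = NULL) {
  ape::read.tree(text = write_newick(t, support = support))
}

#' Uniform random unrooted binary topology
#'
#' Grows the tree by attaching each successive taxon to a uniformly chosen
#' edge, which yields the uniform distribution over labelled unrooted binary
#' topologies.  Uses R's RNG stream.
#'
#' @param n number of taxa (>= 4).
#' @param tip_label optional labels, default `t1..tn`.
#' @return an `mptree`.
#' @export
random_tree <- function(n, tip_label = paste0("t", seq_len(n))) {
  if (n < 4L) stop("need at least 4 taxa")
  nb <- matrix(0L, 2L * n - 2L, 3L)
  c0 <- n + 1L
  nb[c0, ] <- c(1L, 2L, 3L)
  nb[1L, 1L] <- c0; nb[2L, 1L] <- c0; nb[3L, 1L] <- c0
  for (tnew in 4L:n) {
    edges <- edge_list(nb)
    e <- edges[[sample.int(length(edges), 1L)]]
    q <- n + tnew - 2L
    nb <- attach_tip(nb, e[1L], e[2L], tnew, q)
  }
  mptree(nb, tip_label)
}

# list of edges (a, b) with a < b, deterministic order
edge_list <- function(nb) {
  out <- list()
  for (v in seq_len(nrow(nb))) {
    for (u in nb[v, ]) if (u > v) out[[length(out) + 1L]] <- c(v, u)
  }
  out
}

# subdivide edge (a, b) with new internal node q and hang tip `tip` on q
attach_tip <- function(nb, a, b, tip, q) {
  nb[a, nb[a, ] == b] <- q
  nb[b, nb[b, ] == a] <- q
  nb[q, ] <- c(tip, a, b)
  nb[tip, 1L] <- q
  nb
}
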