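#' Enumerate SPR moves within a radius
#'
#' A move prunes the subtree on the `s` side of edge `(p, s)` (`p` must be
#' internal), smooths `p` out and regrafts onto edge `{a, b}` of the
#' remainder.  `dist` counts the nodes on the path between the original
#' attachment edge and the regraft edge (adjacent edges have distance 1);
#' only moves with `dist <= radius` are returned, and no returned move
#' recreates the current topology.
#'
#' @param t an `mptree`.
#' @param radius maximum prune-to-regraft node distance (`Inf` for all).
#' @return integer matrix with columns `p`, `s`, `a`, `b`, `dist`; one row
#'   per move.
#' @export
spr_neighbors <- function(t, radius = Inf) {
  if (radius < 1) stop("radius must be >= 1")
  r <- if (is.finite(radius)) as.integer(radius) else nrow(t$nb)
  c_spr_moves(t$nb, t$ntip, r)
}

#' Apply one SPR move
#'
#' @param t an `mptree`.
#' @param move a single row of [spr_neighbors()] output (or a vector with
#'   named entries `p`, `s`, `a`, `b`).
#' @return the rearranged `mptree`.
#' @export
apply_spr <- function(t, move) {
  move <- as.integer(move[c("p", "s", "a", "b")])
  if (anyNA(move) || any(move < 1L) || any(move > nrow(t$nb)))
    stop("malformed SPR move: need node ids named p, s, a, b")
  nb <- c_apply_spr(t$nb, t$ntip, move[1L], move[2L], move[3L], move[4L])
  mptree(nb, t$tip_label)
}

#' Best-improvement SPR hill climbing
#'
#' Repeatedly applies the best strictly score-improving SPR move within the
#' radius until none exists.  The first move in enumeration order wins ties
#' among equal improvements, so the climb is deterministic given the start
#' tree.  The weighted total is monotonically non-increasing.
#'
#' @inheritParams score_tree
#' @param radius SPR radius (default 6).
#' @param collect when `TRUE`, also return every accepted intermediate tree
#'   (the last one is the returned local optimum) with its per-pattern
#'   scores -- the trees "encountered" during the climb that the bootstrap
#'   machinery consumes.
#' @return list with `tree`, `scores`, `total`, `start_scores`,
#'   `start_total` and (if `collect`) `visited`, a list of
#'   `list(tree, scores, total)`.
#' @export
hill_climb_spr <- function(t, pa, cm, radius = 6, weights = NULL,
                           collect = FALSE) {
  if (!setequal(t$tip_label, pa$taxa))
    stop("tree tips do not match alignment taxa")
  w <- as.numeric(if (is.null(weights)) pa$weights else weights)
  pat <- pa$codes[match(t$tip_label, pa$taxa), , drop = FALSE]
  r <- if (is.finite(radius)) as.integer(radius) else nrow(t$nb)
  res <- c_hill_climb(t$nb, t$ntip, pat, cm$cost, cm$uniform, w, r)
  out <- list(tree = mptree(res$tree, t$tip_label),
              scores = res$scores, total = res$total,
              start_scores = res$start_scores,
              start_total = res$start_total)
  if (collect) {
    out$visited <- Map(function(nb, sc, tt)
      list(tree = mptree(nb, t$tip_label), scores = sc, total = tt),
      res$visited, res$visited_scores, as.list(res$visited_totals))
  }
  out
}

#' Randomized stepwise-addition starting tree
#'
#' Taxa are inserted in a random order; each new taxon is attached to the
#' edge minimizing the resulting weighted parsimony total, ties broken
#' uniformly at random.  All randomness flows through R's RNG stream.
#'
#' @inheritParams score_tree
#' @return an `mptree` over `pa$taxa`.
#' @export
random_stepwise_addition <- function(pa, cm, weights = NULL) {
  n <- length(pa$taxa)
  ord <- sample.int(n)
  w <- as.numeric(if (is.null(weights)) pa$weights else weights)
  nb <- c_stepwise_addition(n, pa$codes, cm$cost, cm$uniform, w, ord)
  mptree(nb, pa$taxa)
}

#' Random NNI perturbation
#'
#' Selects `ceiling(fraction * (n - 3))` internal edges uniformly without
#' replacement and applies at each one of its two nearest-neighbour
#' interchanges, chosen uniformly.
#'
#' @param t an `mptree`.
#' @param fraction fraction of internal edges to rearrange, in (0, 1].
#' @return the perturbed `mptree`.
#' @export
random_nni_perturb <- function(t, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- t$ntip
  # identify internal edges by the split they induce: an NNI across an edge
  # changes only that edge's split, so the remaining chosen edges keep their
  # identity while the adjacency table mutates
  keys <- names(internal_edges(t))
  stopifnot(length(keys) == n - 3L)
  ne <- ceiling(fraction * length(keys))
  chosen <- keys[sample.int(length(keys), ne)]
  for (key in chosen) {
    nb <- t$nb
    e <- internal_edges(t)[[key]]
    u <- e[1L]
    v <- e[2L]
    ou <- setdiff(nb[u, ], v)
    ov <- setdiff(nb[v, ], u)
    swap_u <- ou[2L]
    swap_v <- ov[sample.int(2L, 1L)]
    nb[u, nb[u, ] == swap_u] <- swap_v
    nb[v, nb[v, ] == swap_v] <- swap_u
    nb[swap_u, nb[swap_u, ] == u] <- v
    nb[swap_v, nb[swap_v, ] == v] <- u
    t <- mptree(nb, t$tip_label)
  }
  t
}

# internal (non-pendant) edges keyed by their split; value c(parent, child)
# with respect to a rooting at tip 1
internal_edges <- function(t) {
  n <- t$ntip
  ord <- tree_orders(t, root = 1L)
  parent <- ord$parent
  clades <- vector("list", nrow(t$nb))
  out <- list()
  for (v in ord$postorder) {
    if (v <= n) { clades[[v]] <- v; next }
    kids <- t$nb[v, ][t$nb[v, ] > 0L & t$nb[v, ] != parent[v]]
    cl <- sort(unlist(clades[kids]))
    clades[[v]] <- cl
    if (parent[v] > n && length(cl) >= 2L && length(cl) <= n - 2L)
      out[[paste(cl, collapse = ",")]] <- c(parent[v], v)
  }
  out
}
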