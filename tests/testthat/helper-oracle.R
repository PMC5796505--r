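# Independent oracles and fixture builders.  Everything here avoids the
# package's scoring/search code paths: scores come from exhaustive
# minimization over internal-node state assignments, topologies from
# explicit enumeration.

# brute-force parsimony score of one pattern: minimize total edge cost over
# all state assignments to internal nodes (and to missing-data leaves)
oracle_score <- function(t, codes, cost) {
  n <- t$ntip
  codes <- as.integer(codes)
  free <- c((n + 1L):(2L * n - 2L), which(codes[seq_len(n)] == 0L))
  S <- nrow(cost)
  edges <- do.call(rbind, parsboot:::edge_list(t$nb))
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(free))))
  asg <- matrix(rep(c(codes, rep(1L, nrow(t$nb) - n)), each = nrow(grid)),
                nrow = nrow(grid))
  asg[, free] <- grid
  tot <- numeric(nrow(grid))
  for (e in seq_len(nrow(edges)))
    tot <- tot + cost[cbind(asg[, edges[e, 1L]], asg[, edges[e, 2L]])]
  min(tot)
}

# Faster exhaustive oracle: enumerate internal-node assignments only.
# A missing-data leaf contributes 0 (it can copy its neighbour's state,
# and the diagonal is 0), so the grid never grows with missing data.
make_oracle <- function(t, cost) {
  n <- t$ntip
  internal <- (n + 1L):(2L * n - 2L)
  edges <- do.call(rbind, parsboot:::edge_list(t$nb))
  S <- nrow(cost)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  cm <- function(v) match(v, internal)
  leaf_e <- edges[pmin(edges[, 1], edges[, 2]) <= n, , drop = FALSE]
  int_e <- edges[pmin(edges[, 1], edges[, 2]) > n, , drop = FALSE]
  base <- numeric(nrow(grid))
  for (e in seq_len(nrow(int_e)))
    base <- base + cost[cbind(grid[, cm(int_e[e, 1])],
                              grid[, cm(int_e[e, 2])])]
  pcol <- lapply(seq_len(nrow(leaf_e)), function(e)
    grid[, cm(max(leaf_e[e, ]))])
  leaves <- vapply(seq_len(nrow(leaf_e)), function(e) min(leaf_e[e, ]),
                   numeric(1))
  function(codes) {
    tot <- base
    for (e in seq_along(leaves)) {
      st <- codes[leaves[e]]
      if (st > 0L) tot <- tot + cost[st + (pcol[[e]] - 1L) * S]
    }
    min(tot)
  }
}

# Eq.1-style weighted total via the brute-force scorer
oracle_total <- function(t, pa, cost, weights = pa$weights) {
  s <- vapply(seq_len(pa$k), function(i) oracle_score(t, pa$codes[, i], cost),
              numeric(1L))
  sum(s * as.numeric(weights))
}

# every unrooted binary topology on n labelled tips (3, 15, 105, ... trees)
all_topologies <- function(n, labels = paste0("t", seq_len(n))) {
  nb0 <- matrix(0L, 2L * n - 2L, 3L)
  nb0[n + 1L, ] <- 1:3
  nb0[1L, 1L] <- nb0[2L, 1L] <- nb0[3L, 1L] <- n + 1L
  acc <- list(nb0)
  if (n >= 4L) {
    for (tnew in 4L:n) {
      nxt <- list()
      for (nb in acc)
        for (e in parsboot:::edge_list(nb))
          nxt[[length(nxt) + 1L]] <-
            parsboot:::attach_tip(nb, e[1L], e[2L], tnew, n + tnew - 2L)
      acc <- nxt
    }
  }
  lapply(acc, mptree, tip_label = labels)
}

topo_sig <- function(t) paste(sort(split_keys(t)), collapse = "|")

# random pattern codes over n tips: 0 = missing
random_pattern <- function(n, S = 4L, miss = 0.1) {
  p <- sample.int(S, n, replace = TRUE)
  p[stats::runif(n) < miss] <- 0L
  p
}

# small alignment from explicit column strings ("AACC", ...)
aln_from_columns <- function(cols, taxa = NULL, alphabet = "dna") {
  n <- nchar(cols[[1L]])
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  mat <- do.call(cbind, strsplit(cols, ""))
  parsboot:::new_alignment(taxa, apply(mat, 1L, paste, collapse = ""),
                           alphabet)
}

# nontrivial splits of t projected onto the tip subset `keep`, canonical keys
restrict_splits <- function(t, keep) {
  keep <- sort(keep)
  keys <- character(0)
  for (k in split_keys(t)) {
    side <- intersect(as.integer(strsplit(k, ",")[[1L]]), keep)
    if (length(side) < 2L || length(side) > length(keep) - 2L) next
    if (keep[1L] %in% side) side <- setdiff(keep, side)
    if (length(side) < 2L) next
    keys <- c(keys, paste(side, collapse = ","))
  }
  sort(unique(keys))
}

# SPR-reachability oracle: T2 is one SPR from T1 iff some taxon subset X
# (1 <= |X| <= n-2) hangs as a pendant subtree in both trees with the same
# internal shape, and the trees agree once X is collapsed to a single leaf.
oracle_spr_reachable <- function(t1, t2) {
  n <- t1$ntip
  if (topo_sig(t1) == topo_sig(t2)) return(FALSE)
  sides <- function(t) {
    out <- lapply(split_keys(t), function(k) as.integer(strsplit(k, ",")[[1L]]))
    out <- c(out, lapply(out, function(s) setdiff(seq_len(n), s)))
    out <- c(out, as.list(seq_len(n)))
    out[lengths(out) <= n - 2L]
  }
  sig1 <- vapply(sides(t1), paste, "", collapse = ",")
  sig2 <- vapply(sides(t2), paste, "", collapse = ",")
  for (xs in intersect(sig1, sig2)) {
    X <- as.integer(strsplit(xs, ",")[[1L]])
    comp <- setdiff(seq_len(n), X)
    if (!identical(restrict_splits(t1, comp),
                   restrict_splits(t2, comp))) next
    if (length(X) >= 3L) {               # pruned subtree keeps its shape
      keep_x <- sort(c(X, comp[1L]))
      if (!identical(restrict_splits(t1, keep_x),
                     restrict_splits(t2, keep_x))) next
    }
    return(TRUE)
  }
  FALSE
}

# simulated DNA fixture used across tests
sim_fixture <- function(n, sites, prob = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- evolve_alignment(n = n, sites = sites, subst_prob = prob)
  list(pa = compress_informative(sim$alignment), aln = sim$alignment,
       tree = sim$tree)
}
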