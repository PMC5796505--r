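#' Generate bootstrap replicates as resampled pattern weights
#'
#' Each replicate is a multinomial draw of the `m` informative site slots
#' with per-pattern probabilities `d_i / m` -- the weight-vector equivalent
#' of resampling alignment columns with replacement.  Replicates never
#' materialize resampled alignments: the weighted-sum identity makes the
#' weight vector sufficient.
#'
#' @param pa a `pattern_alignment`.
#' @param B number of replicates (>= 1; 1000 in a typical analysis).
#' @return an object of class `bootstrap_replicates`: list with `W`
#'   (`k x B` integer weight matrix), `best_score` (numeric `B`, `Inf`),
#'   `best_tree` (list of `B` nulls), `B`.
#' @export
make_replicates <- function(pa, B) {
  if (B < 1L) stop("B must be >= 1")
  W <- stats::rmultinom(B, size = pa$m, prob = pa$weights / pa$m)
  structure(list(W = W, B = as.integer(B),
                 best_score = rep(Inf, B),
                 best_tree = vector("list", B),
                 order = NULL, bounds = NULL, minbw = NULL),
            class = "bootstrap_replicates")
}

#' @export
print.bootstrap_replicates <- function(x, ...) {
  cat(sprintf("%d bootstrap replicates over %d patterns (%d scored)\n",
              x$B, nrow(x$W), sum(is.finite(x$best_score))))
  invisible(x)
}

#' Attach the abort machinery to a replicate set
#'
#' Stores the fixed pattern evaluation order and the per-pattern lower
#' bounds, and precomputes each replicate's bound total
#' `sum_i MP_min(D_i) * w_i` used by the early-abort test.
#'
#' @param reps a `bootstrap_replicates` object.
#' @param order pattern order from [replicate_order()].
#' @param bounds per-pattern lower bounds from [pattern_bounds()].
#' @return the updated `bootstrap_replicates`.
#' @export
arm_replicates <- function(reps, order, bounds) {
  stopifnot(length(order) == nrow(reps$W), length(bounds) == nrow(reps$W))
  reps$order <- as.integer(order)
  reps$bounds <- as.integer(bounds)
  reps$minbw <- as.numeric(colSums(reps$W * as.numeric(bounds)))
  reps
}

#' Offer a tree to every bootstrap replicate
#'
#' Evaluates the tree's replicate scores (exact weighted sums of its
#' per-pattern scores) against each replicate's incumbent and stores the
#' tree wherever it strictly improves; ties keep the incumbent.  With
#' `use_abort` the evaluation scans patterns in the stored order and stops
#' early once the partial score plus the lower-bound tail already exceeds
#' the incumbent -- this never changes which trees win.
#'
#' @param reps an armed `bootstrap_replicates` object.
#' @param tree the offered `mptree`.
#' @param scores its per-pattern scores on the original alignment.
#' @param use_abort logical.
#' @return the updated `bootstrap_replicates`.
#' @export
offer_tree <- function(reps, tree, scores, use_abort = TRUE) {
  if (is.null(reps$order)) stop("replicates not armed: call arm_replicates()")
  res <- c_reps_offer(as.integer(scores), reps$W, reps$order, reps$bounds,
                      reps$minbw, reps$best_score, use_abort)
  reps$best_score <- res$best
  for (b in which(res$improved)) reps$best_tree[[b]] <- tree
  reps
}

#' Refine the per-replicate best trees
#'
#' For each replicate, hill-climbs from its current best tree under that
#' replicate's weights and keeps the refined tree when it scores strictly
#' better; scores never worsen.  Refinement is essential: supports computed
#' from unrefined trees are over-confident.
#'
#' @param reps a `bootstrap_replicates` with all best trees set.
#' @inheritParams hill_climb_spr
#' @return the updated `bootstrap_replicates`.
#' @export
refine <- function(reps, pa, cm, radius = 6) {
  for (b in seq_len(reps$B)) {
    tb <- reps$best_tree[[b]]
    if (is.null(tb))
      stop("internal error: replicate ", b, " has no tree (search produced no qualifying tree)")
    res <- hill_climb_spr(tb, pa, cm, radius = radius,
                          weights = reps$W[, b])
    if (res$total < reps$best_score[b]) {
      reps$best_tree[[b]] <- res$tree
      reps$best_score[b] <- res$total
    }
  }
  reps
}

# split keys of every replicate tree, tips indexed against `taxa`
replicate_split_counts <- function(reps, taxa) {
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_len(reps$B)) {
    keys <- split_keys(remap_tips(reps$best_tree[[b]], taxa))
    for (key in keys)
      assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
             counts)
  }
  counts
}

#' Map bootstrap supports onto the best tree
#'
#' Annotates each nontrivial split of the best tree with the percentage of
#' replicate trees containing it.  Pendant edges carry no support.
#'
#' @param best the best `mptree` found on the original alignment.
#' @param reps a refined `bootstrap_replicates`.
#' @return an object of class `supported_tree`: list with `tree`, `support`
#'   (named numeric, exact percentages keyed by split) and `B`.
#' @export
support_on_best_tree <- function(best, reps) {
  counts <- replicate_split_counts(reps, best$tip_label)
  keys <- split_keys(best)
  support <- vapply(keys, function(key) {
    100 * (if (exists(key, counts)) get(key, counts) else 0L) / reps$B
  }, numeric(1L))
  names(support) <- keys
  structure(list(tree = best, support = support, B = reps$B),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("best tree with supports from %d replicates\n", x$B))
  cat(write_newick(x$tree, support = x$support), "\n")
  invisible(x)
}

#' Majority-rule consensus of the bootstrap trees
#'
#' Includes every split occurring in more than `threshold` percent of the
#' replicate trees; the result may contain polytomies.  For
#' `threshold >= 50` the retained splits are pairwise compatible by the
#' majority-rule guarantee, so a tree always exists.
#'
#' @param reps a refined `bootstrap_replicates`.
#' @param taxa taxon ordering for the output.
#' @param threshold percentage threshold (default 50; values below 50 are
#'   rejected since the splits could conflict).
#' @return list with `tree` (an `ape::phylo`, possibly multifurcating, with
#'   integer support node labels), `splits` (kept split keys) and `support`
#'   (their exact percentages).
#' @export
majority_consensus <- function(reps, taxa, threshold = 50) {
  if (threshold < 50) stop("threshold below 50 can yield incompatible splits")
  counts <- replicate_split_counts(reps, taxa)
  keys <- ls(counts)
  pct <- vapply(keys, function(k) 100 * get(k, counts) / reps$B, numeric(1L))
  keep <- pct > threshold
  keys <- keys[keep]
  pct <- pct[keep]
  nwk <- consensus_newick(keys, pct, taxa)
  list(tree = ape::read.tree(text = nwk), splits = keys, support = pct)
}

# build a (possibly multifurcating) newick string from a laminar family of
# splits, each given as the comma-separated tip-index set not containing
# tip 1; supports become internal node labels
consensus_newick <- function(keys, pct, taxa) {
  n <- length(taxa)
  sets <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1L]]))
  ord <- order(lengths(sets))
  sets <- sets[ord]
  pct <- pct[ord]
  # parent of each set = smallest strictly-containing set (or the root)
  parent <- integer(length(sets))
  for (i in seq_along(sets)) {
    parent[i] <- 0L
    for (j in seq_along(sets)) {
      if (j == i || length(sets[[j]]) <= length(sets[[i]]))
        next
      if (all(sets[[i]] %in% sets[[j]])) { parent[i] <- j; break }
    }
  }
  tip_parent <- rep(0L, n)
  for (tip in seq_len(n)) {
    holders <- which(vapply(sets, function(s) tip %in% s, logical(1L)))
    if (length(holders)) tip_parent[tip] <- holders[1L] # smallest set first
  }
  rec <- function(i) {
    kids <- c(taxa[which(tip_parent == i)],
              vapply(which(parent == i), rec, character(1L)))
    if (i == 0L) return(paste0("(", paste(kids, collapse = ","), ");"))
    paste0("(", paste(kids, collapse = ","), ")",
           sprintf("%d", floor(pct[i] + 0.5)))
  }
  rec(0L)
}
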