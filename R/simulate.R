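#' Simulate an alignment by evolving characters along a tree
#'
#' Synthetic-fixture generator: the root sequence is uniform over the state
#' alphabet and every site mutates independently on each edge with
#' probability `subst_prob`, jumping to a uniformly chosen different state
#' (a symmetric Jukes-Cantor-like process; real data features such as gap
#' patterns, rate heterogeneity or codon structure are deliberately not
#' modelled).  Pure function of its arguments and R's RNG state.
#'
#' @param n number of taxa (used when `tree` is `NULL`).
#' @param sites number of sites.
#' @param subst_prob per-edge per-site substitution probability, in (0, 1).
#' @param alphabet `"dna"` or `"protein"`.
#' @param tree optional true `mptree`; default a [random_tree()] on `n` taxa.
#' @return list with `alignment` (an `mp_alignment`) and `tree` (the true
#'   `mptree`).
#' @export
evolve_alignment <- function(n = NULL, sites, subst_prob,
                             alphabet = c("dna", "protein"), tree = NULL) {
  alphabet <- match.arg(alphabet)
  if (subst_prob <= 0 || subst_prob >= 1)
    stop("subst_prob must be in (0, 1)")
  if (is.null(tree)) tree <- random_tree(n)
  n <- tree$ntip
  states <- alphabet_states(alphabet)
  S <- length(states)
  root <- tree$nb[1L, 1L] # internal node adjacent to tip 1
  ord <- tree_orders(tree, root = root)
  seqs <- matrix(0L, nrow(tree$nb), sites)
  seqs[root, ] <- sample.int(S, sites, replace = TRUE)
  for (v in rev(ord$postorder)) { # parents before children
    if (v == root) next
    p <- ord$parent[v]
    x <- seqs[p, ]
    hit <- which(stats::runif(sites) < subst_prob)
    if (length(hit)) {
      shift <- sample.int(S - 1L, length(hit), replace = TRUE)
      x[hit] <- 1L + (x[hit] - 1L + shift) %% S
    }
    seqs[v, ] <- x
  }
  leaf_seqs <- vapply(seq_len(n), function(i)
    paste(states[seqs[i, ]], collapse = ""), character(1L))
  list(alignment = new_alignment(tree$tip_label, leaf_seqs, alphabet),
       tree = tree)
}
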