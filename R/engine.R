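#' Parsimony score of a tree on a pattern alignment
#'
#' Computes the per-pattern scores `MP(T | D_i)` and the weighted total
#' `sum_i MP(T | D_i) * d_i`.  Uniform cost models are scored with the Fitch
#' set algorithm, general step matrices with the Sankoff dynamic program;
#' both are invariant to the internal rooting (scoring roots at tip 1).
#'
#' @param t an `mptree` whose tip labels equal the alignment taxa.
#' @param pa a `pattern_alignment`.
#' @param cm a `cost_model`.
#' @param weights optional override of the pattern weights (e.g. ratchet or
#'   bootstrap weights); default the original `pa$weights`.
#' @param method `"auto"` (Fitch iff the model is uniform), `"fitch"` or
#'   `"sankoff"`.
#' @return list with integer vector `scores` (length `pa$k`) and numeric
#'   `total`.
#' @export
score_tree <- function(t, pa, cm, weights = NULL,
                       method = c("auto", "fitch", "sankoff")) {
  method <- match.arg(method)
  if (!setequal(t$tip_label, pa$taxa) || t$ntip != length(pa$taxa))
    stop("tree tips do not match alignment taxa")
  if (method == "fitch" && !cm$uniform)
    stop("the Fitch algorithm requires a uniform cost model")
  uniform <- switch(method, auto = cm$uniform, fitch = TRUE, sankoff = FALSE)
  pat <- pa$codes[match(t$tip_label, pa$taxa), , drop = FALSE]
  scores <- c_score_tree(t$nb, t$ntip, pat, cm$cost, uniform, 1L)
  w <- if (is.null(weights)) pa$weights else weights
  list(scores = scores, total = sum(scores * as.numeric(w)))
}

#' Fitch score of a single pattern
#'
#' @param t an `mptree`.
#' @param pattern character state vector ordered as `t$tip_label` (characters
#'   outside the alphabet count as missing data), or integer codes.
#' @param alphabet alphabet of the pattern (ignored for integer input).
#' @return non-negative integer.
#' @export
score_pattern_fitch <- function(t, pattern, alphabet = "dna") {
  states <- alphabet_states(alphabet)
  codes <- if (is.character(pattern)) encode_pattern(pattern, states)
           else as.integer(pattern)
  cm <- uniform_cost(alphabet)
  c_score_tree(t$nb, t$ntip, matrix(codes, ncol = 1L), cm$cost, TRUE, 1L)[1L]
}

#' Sankoff score of a single pattern under an arbitrary step matrix
#'
#' @param t an `mptree`.
#' @param pattern character state vector or integer codes (0 = missing).
#' @param cm a `cost_model`.
#' @return non-negative integer.
#' @export
score_pattern_sankoff <- function(t, pattern, cm) {
  codes <- if (is.character(pattern)) encode_pattern(pattern, cm$states)
           else as.integer(pattern)
  c_score_tree(t$nb, t$ntip, matrix(codes, ncol = 1L), cm$cost, FALSE, 1L)[1L]
}

#' Bootstrap-replicate score from precomputed pattern scores
#'
#' The parsimony score of a tree on a resampled alignment is exactly the
#' weighted sum of its per-pattern scores with the resampled weights --
#' no rescoring needed, and the result is exact, not approximate.
#'
#' @param scores integer per-pattern scores of a fixed tree.
#' @param w non-negative resampled weight vector of the same length.
#' @return numeric score.
#' @export
reps_score <- function(scores, w) {
  if (length(scores) != length(w)) stop("length mismatch")
  if (any(w < 0)) stop("negative bootstrap weight")
  sum(as.numeric(scores) * as.numeric(w))
}

#' Replicate-score with early abort against an incumbent
#'
#' Scans patterns in a fixed order accumulating the partial exact score plus
#' the lower-bound tail `sum_{i>j} MP_min(D_i) * w_i`; aborts as soon as this
#' running lower bound strictly exceeds `best` (the incumbent replicate
#' score), since the tree then cannot improve that replicate.
#'
#' @param scores per-pattern scores of the offered tree.
#' @param w resampled weights.
#' @param order pattern index permutation (descending first-tree scores; see
#'   [replicate_order()]).
#' @param bounds per-pattern lower bounds ([pattern_bounds()]).
#' @param best incumbent score (`Inf` disables aborting).
#' @return list with `aborted` (logical) and `score` (exact score, or `NA`
#'   when aborted).
#' @export
reps_score_with_abort <- function(scores, w, order, bounds, best) {
  k <- length(scores)
  stopifnot(length(w) == k, length(bounds) == k,
            setequal(order, seq_len(k)))
  run <- sum(as.numeric(bounds) * as.numeric(w))
  for (i in order) {
    run <- run + (scores[i] - bounds[i]) * w[i]
    if (run > best) return(list(aborted = TRUE, score = NA_real_))
  }
  list(aborted = FALSE, score = run)
}

#' Fixed pattern evaluation order for replicate scoring
#'
#' Patterns are scanned in descending order of their scores on the first
#' tree built in the initial search step, so that high-cost patterns
#' accumulate early and aborts fire as soon as possible.  Ties break by
#' ascending pattern index (reproducibility).
#'
#' @param first_tree_scores per-pattern scores of the first constructed tree.
#' @return integer permutation of `seq_along(first_tree_scores)`.
#' @export
replicate_order <- function(first_tree_scores) {
  order(-first_tree_scores, seq_along(first_tree_scores))
}
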