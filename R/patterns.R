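#' Compress an alignment into weighted parsimony-informative site patterns
#'
#' A column is parsimony informative when at least two distinct non-missing
#' states are each present in at least two sequences; only such columns can
#' differ in cost between topologies under a uniform cost matrix.  Identical
#' columns (exact state-vector equality, including missing codes; no
#' canonicalisation up to state relabelling, since non-uniform costs are not
#' relabelling-symmetric) are merged and their counts summed.
#'
#' @param a an `mp_alignment` with at least 4 taxa.
#' @return An object of class `pattern_alignment` with elements
#'   `codes` (integer matrix, taxa x k; 0 = missing, `1..S` = state index),
#'   `weights` (integer, k), `m` (total informative sites), `taxa`,
#'   `alphabet`, `states`.
#' @export
compress_informative <- function(a) {
  stopifnot(inherits(a, "mp_alignment"))
  if (a$n < 4L) stop("need at least 4 taxa for a tree search")
  states <- alphabet_states(a$alphabet)
  chars <- do.call(rbind, strsplit(a$seqs, ""))
  codes <- matrix(match(chars, states, nomatch = 0L),
                  nrow = a$n, ncol = a$length)
  informative <- vapply(seq_len(ncol(codes)), function(j) {
    tab <- tabulate(codes[, j], nbins = length(states))
    sum(tab >= 2L) >= 2L
  }, logical(1L))
  m <- sum(informative)
  if (m == 0L)
    stop("no signal: alignment has no parsimony-informative sites")
  codes <- codes[, informative, drop = FALSE]
  key <- apply(codes, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  weights <- as.integer(table(factor(key, levels = key[first])))
  structure(list(codes = codes[, first, drop = FALSE],
                 weights = weights, m = m, k = sum(first),
                 taxa = a$taxa, alphabet = a$alphabet, states = states),
            class = "pattern_alignment")
}

#' @export
print.pattern_alignment <- function(x, ...) {
  cat(sprintf("%d informative sites in %d patterns over %d taxa (%s)\n",
              x$m, x$k, length(x$taxa), toupper(x$alphabet)))
  invisible(x)
}

# encode a character state vector (ordered as `taxa`) to integer codes
encode_pattern <- function(pattern, states) {
  match(toupper(pattern), states, nomatch = 0L)
}
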