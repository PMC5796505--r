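#' Step (cost) matrices for parsimony scoring
#'
#' A cost model is a symmetric non-negative integer step matrix with zero
#' diagonal that satisfies the triangle inequality
#' `cost[a,c] <= cost[a,b] + cost[b,c]` (required for the minimum-spanning-
#' tree pattern lower bound to be valid).
#'
#' @param cost square integer matrix with state letters as dimnames.
#' @param states ordered state alphabet.
#' @return an object of class `cost_model` with elements `states`, `cost`
#'   and `uniform` (TRUE when all off-diagonal costs equal 1, enabling the
#'   Fitch algorithm).
#' @export
cost_model <- function(cost, states = colnames(cost)) {
  cost <- as.matrix(cost)
  storage.mode(cost) <- "integer"
  S <- length(states)
  if (!all(dim(cost) == S)) stop("cost matrix must be square over the states")
  if (any(cost < 0L)) stop("costs must be non-negative")
  if (any(diag(cost) != 0L)) stop("cost diagonal must be zero")
  if (!isTRUE(all.equal(cost, t(cost))))
    stop("asymmetric cost matrix rejected: unrooted-tree parsimony assumes symmetric costs")
  if (!triangle_holds(cost))
    stop("cost matrix violates the triangle inequality; apply triangle_closure() first")
  dimnames(cost) <- list(states, states)
  off <- cost[row(cost) != col(cost)]
  structure(list(states = states, cost = cost,
                 uniform = all(off == 1L)),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("%s cost model over %d states (%s)\n",
              if (x$uniform) "uniform" else "non-uniform",
              length(x$states), paste(x$states, collapse = "")))
  invisible(x)
}

#' All-pairs shortest-path closure of a cost matrix
#'
#' Floyd-Warshall closure; the minimal repair that makes a symmetric matrix
#' satisfy the triangle inequality.  Idempotent and never increases an entry.
#'
#' @param cost square numeric matrix.
#' @return closed matrix.
#' @export
triangle_closure <- function(cost) {
  S <- nrow(cost)
  for (b in seq_len(S)) {
    via <- outer(cost[, b], cost[b, ], `+`)
    cost <- pmin(cost, via)
  }
  cost
}

triangle_holds <- function(cost) {
  all(triangle_closure(cost) == cost)
}

#' Uniform cost model (all substitutions cost 1)
#'
#' @inheritParams alphabet_states
#' @return a `cost_model`.
#' @export
uniform_cost <- function(alphabet = c("dna", "protein")) {
  st <- alphabet_states(alphabet)
  S <- length(st)
  m <- matrix(1L, S, S, dimnames = list(st, st))
  diag(m) <- 0L
  cost_model(m, st)
}

#' DNA transition/transversion cost model
#'
#' Transitions (A<->G, C<->T) cost 1, transversions cost 2.
#'
#' @return a `cost_model`.
#' @export
dna_titv_cost <- function() {
  st <- alphabet_states("dna")
  m <- matrix(2L, 4L, 4L, dimnames = list(st, st))
  diag(m) <- 0L
  m["A", "G"] <- m["G", "A"] <- 1L
  m["C", "T"] <- m["T", "C"] <- 1L
  cost_model(m, st)
}

#' Protein minimum-nucleotide-change cost model
#'
#' The raw cost between two amino acids is the smallest Hamming distance
#' between any pair of their codons under the standard genetic code (stop
#' codons excluded).  The raw matrix violates the triangle inequality for
#' some triples, so it is repaired by all-pairs shortest-path closure.
#'
#' @param genetic_code named character vector mapping codons to amino-acid
#'   letters (default: the standard code from Biostrings).
#' @return a `cost_model` over the 20 amino acids.
#' @export
protein_min_nt_cost <- function(genetic_code = Biostrings::GENETIC_CODE) {
  st <- alphabet_states("protein")
  codons <- lapply(st, function(aa) names(genetic_code)[genetic_code == aa])
  if (any(lengths(codons) == 0L)) stop("genetic code table misses amino acids")
  ham <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  S <- length(st)
  m <- matrix(0L, S, S, dimnames = list(st, st))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j <= i) next
      d <- min(outer(codons[[i]], codons[[j]], Vectorize(ham)))
      m[i, j] <- m[j, i] <- as.integer(d)
    }
  }
  m <- triangle_closure(m)
  storage.mode(m) <- "integer"
  cost_model(m, st)
}

#' Read a user step matrix
#'
#' Plain-text format: first line the state letters (whitespace-separated),
#' then a full square integer matrix.  Asymmetric matrices and matrices
#' violating the triangle inequality are rejected.
#'
#' @param path file path.
#' @return a `cost_model`.
#' @export
read_cost_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  st <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  S <- length(st)
  if (length(lines) < S + 1L) stop("cost matrix file: too few rows")
  rows <- lapply(lines[2:(S + 1L)], function(x)
    as.integer(strsplit(trimws(x), "\\s+")[[1L]]))
  if (any(lengths(rows) != S) || anyNA(unlist(rows)))
    stop("cost matrix file: malformed matrix")
  m <- do.call(rbind, rows)
  dimnames(m) <- list(st, st)
  cost_model(m, st)
}

#' Resolve a cost model from a user selector
#'
#' @param cost a `cost_model`, or one of `"uniform"`, `"titv"`,
#'   `"protein_nt"`, or a path to a step-matrix file.
#' @param alphabet alignment alphabet (used for `"uniform"`).
#' @return a `cost_model`.
#' @export
resolve_cost <- function(cost, alphabet = "dna") {
  if (inherits(cost, "cost_model")) return(cost)
  if (cost == "uniform") return(uniform_cost(alphabet))
  if (cost == "titv") return(dna_titv_cost())
  if (cost == "protein_nt") return(protein_min_nt_cost())
  if (file.exists(cost)) return(read_cost_matrix(cost))
  stop("unknown cost model selector: ", cost)
}

#' Per-pattern parsimony lower bound
#'
#' The smallest parsimony score a pattern can attain on any tree: with a
#' uniform cost matrix, the number of distinct observed states minus 1;
#' in general, the total weight of a minimum spanning tree on the complete
#' graph whose nodes are the observed states and whose edge weights are the
#' pairwise costs.  Missing states are excluded; patterns with at most one
#' observed state bound to 0.
#'
#' @param pattern integer code vector (0 = missing) or character state vector.
#' @param cm a `cost_model`.
#' @return non-negative integer.
#' @export
pattern_lower_bound <- function(pattern, cm) {
  if (is.character(pattern)) pattern <- encode_pattern(pattern, cm$states)
  obs <- sort(unique(pattern[pattern > 0L]))
  if (length(obs) <= 1L) return(0L)
  if (cm$uniform) return(length(obs) - 1L)
  mst_weight(cm$cost[obs, obs, drop = FALSE])
}

# Prim's algorithm on a small complete graph given its weight matrix
mst_weight <- function(w) {
  S <- nrow(w)
  intree <- c(TRUE, rep(FALSE, S - 1L))
  dist <- w[1L, ]
  total <- 0L
  for (step in seq_len(S - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(dist[cand])]
    total <- total + dist[v]
    intree[v] <- TRUE
    dist <- pmin(dist, w[v, ])
  }
  as.integer(total)
}

#' Lower bounds for every pattern of a pattern alignment
#'
#' @param pa a `pattern_alignment`.
#' @param cm a `cost_model`.
#' @return integer vector of length `pa$k`.
#' @export
pattern_bounds <- function(pa, cm) {
  vapply(seq_len(pa$k),
         function(i) pattern_lower_bound(pa$codes[, i], cm),
         integer(1L))
}
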