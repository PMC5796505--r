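#' Stopping horizon for the exploration phase
#'
#' The number of sequences rounded up to the nearest hundred: the search
#' stops after this many consecutive unsuccessful hill-climbing steps, so
#' larger taxon sets are searched more thoroughly.
#'
#' @param n number of taxa (>= 4).
#' @return integer multiple of 100.
#' @export
stopping_horizon <- function(n) {
  stopifnot(n >= 4L)
  as.integer(100L * ceiling(n / 100))
}

#' Initialize the candidate tree set
#'
#' Builds `starts` locally optimal trees (randomized stepwise addition
#' followed by SPR hill climbing), sorts them by score and keeps the first
#' `keep` topologically distinct ones as the candidate set -- a small
#' population that preserves diversity for the perturbation phase.  The very
#' first stepwise-addition tree is recorded: its per-pattern scores fix the
#' pattern evaluation order used by replicate scoring.
#'
#' @inheritParams hill_climb_spr
#' @param starts number of independent starts (default 100).
#' @param keep maximum candidate-set size (default 5).
#' @return a `search_state` list with elements `C` (list of `mptree`),
#'   `C_totals`, `S` (score multiset, empty), `mp_max` (`Inf`),
#'   `unsuccessful` (0), `n_prime`, `t_first`, `order`.
#' @export
init_candidate_set <- function(pa, cm, radius = 6, starts = 100L,
                               keep = 5L) {
  finals <- vector("list", starts)
  totals <- numeric(starts)
  t_first <- NULL
  for (i in seq_len(starts)) {
    t0 <- random_stepwise_addition(pa, cm)
    if (i == 1L) t_first <- t0
    res <- hill_climb_spr(t0, pa, cm, radius = radius)
    finals[[i]] <- res$tree
    totals[i] <- res$total
  }
  ord <- order(totals)
  C <- list()
  C_totals <- numeric(0)
  sigs <- character(0)
  for (i in ord) {
    sig <- paste(sort(split_keys(finals[[i]])), collapse = "|")
    if (sig %in% sigs) next
    C <- c(C, finals[i])
    C_totals <- c(C_totals, totals[i])
    sigs <- c(sigs, sig)
    if (length(C) >= keep) break
  }
  first_scores <- score_tree(t_first, pa, cm)$scores
  structure(list(C = C, C_totals = C_totals, C_sigs = sigs,
                 S = numeric(0), S_count = 0L, mp_max = Inf,
                 unsuccessful = 0L,
                 n_prime = stopping_horizon(length(pa$taxa)),
                 t_first = t_first,
                 order = replicate_order(first_scores)),
            class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  cat(sprintf(
    "search state: |C| = %d, best total = %s, MP_max = %s, %d/%d unsuccessful\n",
    length(x$C), format(min(x$C_totals)), format(x$mp_max),
    x$unsuccessful, x$n_prime))
  invisible(x)
}

# ratchet weights: duplicate ceiling(m * fraction) of the m informative site
# slots (honouring pattern multiplicities) by adding +1 to their patterns
ratchet_weights <- function(pa, fraction = 0.5) {
  slots <- rep.int(seq_len(pa$k), pa$weights)
  pick <- sample.int(pa$m, ceiling(pa$m * fraction))
  pa$weights + tabulate(slots[pick], nbins = pa$k)
}

#' Perturb a candidate tree
#'
#' Picks a tree uniformly from the candidate set and, with probability 1/2
#' each, either applies random NNIs to `nni_fraction` of its internal edges,
#' or runs the parsimony ratchet: upweight a random `ratchet_fraction` of
#' the informative sites, hill-climb under the perturbed weights, and return
#' the resulting local optimum.
#'
#' @param state a `search_state`.
#' @inheritParams hill_climb_spr
#' @param nni_fraction fraction of internal edges for the NNI branch.
#' @param ratchet_fraction fraction of sites duplicated by the ratchet.
#' @return an `mptree`.
#' @export
perturb <- function(state, pa, cm, radius = 6, nni_fraction = 0.5,
                    ratchet_fraction = 0.5) {
  tc <- state$C[[sample.int(length(state$C), 1L)]]
  if (stats::runif(1L) < 0.5) {
    random_nni_perturb(tc, nni_fraction)
  } else {
    w <- ratchet_weights(pa, ratchet_fraction)
    hill_climb_spr(tc, pa, cm, radius = radius, weights = w)$tree
  }
}

# lower 10%-quantile of the score multiset, linearly interpolated then
# truncated to an integer floor
lower_quantile_floor <- function(s, p = 0.10) {
  floor(as.numeric(stats::quantile(s, probs = p, names = FALSE, type = 7)))
}

S_CAP <- 100000L

# reservoir-style capped multiset of qualifying tree scores
s_add <- function(state, total) {
  state$S_count <- state$S_count + 1L
  if (length(state$S) < S_CAP) {
    state$S <- c(state$S, total)
  } else if (stats::runif(1L) < S_CAP / state$S_count) {
    state$S[sample.int(S_CAP, 1L)] <- total
  }
  state
}

#' The perturbation / hill-climbing exploration loop
#'
#' Repeats `{perturb -> SPR hill climb on the original weights ->
#' candidate-set update -> MP_max update}` until `n_prime` consecutive
#' steps were unsuccessful (a step succeeds when the climbed tree scores
#' strictly below the current candidate-set minimum).  Every tree accepted
#' during a climb (including the final local optimum) whose total is below
#' the current threshold `MP_max` has its total added to the score set `S`
#' and is handed to `hook(tree, scores, total)` -- the bootstrap machinery.
#' After each step `MP_max` is reset to the lower 10%-quantile of `S`.
#'
#' @param state a `search_state` from [init_candidate_set()].
#' @inheritParams perturb
#' @param hook optional function `(tree, scores, total)` called for each
#'   qualifying tree; its return value is ignored.
#' @param trace when `TRUE`, attach a data frame logging every hook offer
#'   (`iter`, `total`, `mp_max` at the time of the offer).
#' @param verbose print progress every 25 iterations.
#' @return the final `search_state`; element `iterations` holds the number
#'   of perturbation steps executed.
#' @export
exploration_loop <- function(state, pa, cm, radius = 6, hook = NULL,
                             nni_fraction = 0.5, ratchet_fraction = 0.5,
                             trace = FALSE, verbose = FALSE) {
  iter <- 0L
  log <- if (trace) list() else NULL
  while (state$unsuccessful < state$n_prime) {
    iter <- iter + 1L
    tstar <- perturb(state, pa, cm, radius = radius,
                     nni_fraction = nni_fraction,
                     ratchet_fraction = ratchet_fraction)
    climb <- hill_climb_spr(tstar, pa, cm, radius = radius, collect = TRUE)
    visited <- climb$visited
    if (!length(visited)) {
      visited <- list(list(tree = climb$tree, scores = climb$start_scores,
                           total = climb$start_total))
    }
    for (vis in visited) {
      if (vis$total < state$mp_max) {
        state <- s_add(state, vis$total)
        if (!is.null(hook)) hook(vis$tree, vis$scores, vis$total)
        if (trace) log[[length(log) + 1L]] <-
            c(iter = iter, total = vis$total, mp_max = state$mp_max)
      }
    }
    # success test against the candidate set *before* updating it
    success <- climb$total < min(state$C_totals)
    if (climb$total <= max(state$C_totals)) {
      sig <- paste(sort(split_keys(climb$tree)), collapse = "|")
      if (!sig %in% state$C_sigs) {
        if (length(state$C) < 5L) {
          state$C <- c(state$C, list(climb$tree))
          state$C_totals <- c(state$C_totals, climb$total)
          state$C_sigs <- c(state$C_sigs, sig)
        } else {
          worst <- which.max(state$C_totals) # ties: oldest
          state$C[[worst]] <- climb$tree
          state$C_totals[worst] <- climb$total
          state$C_sigs[worst] <- sig
        }
      }
    }
    if (length(state$S)) state$mp_max <- lower_quantile_floor(state$S)
    state$unsuccessful <- if (success) 0L else state$unsuccessful + 1L
    if (verbose && iter %% 25L == 0L)
      message(sprintf("iter %d: best %s, MP_max %s, unsuccessful %d/%d",
                      iter, format(min(state$C_totals)),
                      format(state$mp_max), state$unsuccessful,
                      state$n_prime))
  }
  state$iterations <- iter
  if (trace)
    state$trace <- as.data.frame(do.call(rbind, log))
  state
}

#' Pure maximum-parsimony tree search
#'
#' Runs the full search (candidate-set initialization plus exploration loop)
#' without any bootstrap machinery and returns the best tree found.
#'
#' @inheritParams init_candidate_set
#' @param seed optional RNG seed.
#' @return list with `tree` (best `mptree`), `total`, `state`.
#' @export
mp_search <- function(pa, cm, radius = 6, starts = 100L, keep = 5L,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_candidate_set(pa, cm, radius = radius, starts = starts,
                              keep = keep)
  state <- exploration_loop(state, pa, cm, radius = radius)
  best <- which.min(state$C_totals)
  list(tree = state$C[[best]], total = state$C_totals[best], state = state)
}
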