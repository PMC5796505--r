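quartet <- function() parse_newick("((t1,t2),(t3,t4));")

test_that("Fitch and Sankoff reproduce brute-force scores on canonical cases", {
  t <- quartet()
  u <- uniform_cost("dna")
  tv <- dna_titv_cost()
  cases <- list(
    list(p = c("A", "A", "C", "C"), cm = u,  fitch = TRUE),
    list(p = c("A", "A", "A", "A"), cm = u,  fitch = TRUE),
    list(p = c("A", "?", "C", "C"), cm = u,  fitch = TRUE),
    list(p = c("A", "A", "G", "G"), cm = tv, fitch = FALSE),
    list(p = c("A", "A", "C", "C"), cm = tv, fitch = FALSE))
  for (cs in cases) {
    codes <- parsboot:::encode_pattern(cs$p, cs$cm$states)
    want <- oracle_score(t, codes, cs$cm$cost)
    got <- if (cs$fitch) score_pattern_fitch(t, cs$p)
           else score_pattern_sankoff(t, cs$p, cs$cm)
    expect_equal(got, want)
  }
  # frozen expectations for the canonical quartet patterns
  expect_equal(score_pattern_fitch(t, c("A", "A", "C", "C")), 1L)
  expect_equal(score_pattern_fitch(t, c("A", "A", "A", "A")), 0L)
  expect_equal(score_pattern_fitch(t, c("A", "?", "C", "C")), 1L)
  expect_equal(score_pattern_sankoff(t, c("A", "A", "G", "G"), dna_titv_cost()), 1L)
  expect_equal(score_pattern_sankoff(t, c("A", "A", "C", "C"), dna_titv_cost()), 2L)
})

test_that("Fitch equals Sankoff under uniform cost on random fixtures", {
  set.seed(11)
  u <- uniform_cost("dna")
  for (rep in 1:200) {
    n <- sample(4:9, 1)
    t <- random_tree(n)
    p <- random_pattern(n)
    expect_equal(score_pattern_fitch(t, p),
                 score_pattern_sankoff(t, p, u))
  }
})

test_that("scores are invariant under re-rooting and tip-order permutation", {
  set.seed(12)
  tv <- dna_titv_cost()
  u <- uniform_cost("dna")
  for (rep in 1:20) {
    n <- 7
    t <- random_tree(n)
    p <- random_pattern(n)
    f0 <- score_pattern_fitch(t, p)
    s0 <- score_pattern_sankoff(t, p, tv)
    for (root in c(2L, 5L, n)) {
      expect_equal(parsboot:::c_score_tree(t$nb, n, matrix(p, ncol = 1),
                                           u$cost, TRUE, root)[1], f0)
      expect_equal(parsboot:::c_score_tree(t$nb, n, matrix(p, ncol = 1),
                                           tv$cost, FALSE, root)[1], s0)
    }
    # permute taxon ids: remap tree and pattern together
    perm <- sample(n)
    t2 <- parsboot:::remap_tips(t, t$tip_label[order(perm)])
    expect_equal(score_pattern_fitch(t2, p[order(perm)]), f0)
  }
})

test_that("sankoff agrees with phangorn on protein data without missing states", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  cm <- protein_min_nt_cost()
  n <- 6
  t <- random_tree(n)
  ph <- mptree_to_phylo(t)
  chars <- matrix(sample(cm$states, n * 15, replace = TRUE), nrow = n,
                  dimnames = list(t$tip_label, NULL))
  dat <- phangorn::phyDat(chars, type = "USER", levels = cm$states)
  want <- phangorn::parsimony(ph, dat, method = "sankoff", cost = cm$cost)
  codes <- matrix(match(chars, cm$states), nrow = n)
  got <- sum(parsboot:::c_score_tree(t$nb, n, codes, cm$cost, FALSE, 1L))
  expect_equal(got, as.numeric(want))
})

test_that("score_tree computes Eq.1 totals, linearity and input checks", {
  a <- aln_from_columns(c("AACC", "AACC", "AGAG"))
  pa <- compress_informative(a)
  u <- uniform_cost("dna")
  t <- quartet()
  res <- score_tree(t, pa, u)
  expect_equal(res$scores, c(1L, 2L))
  expect_equal(res$total, 1 * 2 + 2 * 1)
  res3 <- score_tree(t, pa, u, weights = pa$weights * 3)
  expect_equal(res3$scores, res$scores)
  expect_equal(res3$total, res$total * 3)
  bad <- parse_newick("((a,b),(c,d));")
  expect_error(score_tree(bad, pa, u), "match")
})

test_that("replicate scoring is exact and reduces to Eq.1 at original weights", {
  expect_equal(reps_score(c(1L, 2L), c(3, 0)), 3)
  expect_error(reps_score(c(1L, 2L), c(-1, 1)), "negative")
  set.seed(14)
  u <- uniform_cost("dna")
  tv <- dna_titv_cost()
  for (rep in 1:50) {
    fix <- sim_fixture(6, 60, prob = 0.15)
    pa <- fix$pa
    cm <- if (rep %% 2) u else tv
    t <- random_tree(6)
    sc <- score_tree(t, pa, cm)
    expect_equal(reps_score(sc$scores, pa$weights), sc$total)
    w <- as.integer(stats::rmultinom(1, pa$m, pa$weights / pa$m))
    # independent oracle: fold the weights into a brute-force rescoring
    expect_equal(reps_score(sc$scores, w), oracle_total(t, pa, cm$cost, w))
  }
})

test_that("the abort test is valid and returns exact scores when it does not fire", {
  # hand-evaluated example: scan order (1,2), running bound exceeds 40 at j=1
  r <- reps_score_with_abort(scores = c(5L, 1L), w = c(10, 10),
                             order = 1:2, bounds = c(0L, 0L), best = 40)
  expect_true(r$aborted)
  r2 <- reps_score_with_abort(c(5L, 1L), c(10, 10), 1:2, c(0L, 0L),
                              best = Inf)
  expect_false(r2$aborted)
  expect_equal(r2$score, 60)

  set.seed(15)
  for (rep in 1:1000) {
    k <- sample(3:12, 1)
    scores <- sample(0:6, k, replace = TRUE)
    bounds <- pmin(scores, sample(0:3, k, replace = TRUE))
    w <- sample(0:5, k, replace = TRUE)
    best <- sample(0:40, 1)
    ord <- replicate_order(scores)
    exact <- sum(scores * w)
    r <- reps_score_with_abort(scores, w, ord, bounds, best)
    if (r$aborted) expect_gt(exact, best) else expect_equal(r$score, exact)
    # C++ path used by offer_tree agrees with the R reference
    cres <- parsboot:::c_reps_offer(scores, matrix(as.integer(w), ncol = 1),
                                    as.integer(ord), as.integer(bounds),
                                    sum(bounds * w), best, TRUE)
    expect_equal(cres$improved[1], !r$aborted && exact < best)
  }
})

test_that("replicate_order sorts by descending score with index tie-break", {
  expect_equal(replicate_order(c(3L, 5L, 3L, 9L)), c(4L, 2L, 1L, 3L))
})
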