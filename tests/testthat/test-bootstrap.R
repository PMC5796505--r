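armed_fixture <- function(n = 6, sites = 80, B = 30, seed = 51,
                          cost = uniform_cost("dna")) {
  fix <- sim_fixture(n, sites, prob = 0.12, seed = seed)
  set.seed(seed + 1)
  reps <- make_replicates(fix$pa, B)
  t0 <- random_stepwise_addition(fix$pa, cost)
  sc <- score_tree(t0, fix$pa, cost)
  reps <- arm_replicates(reps, replicate_order(sc$scores),
                         pattern_bounds(fix$pa, cost))
  list(fix = fix, reps = reps, t0 = t0, sc = sc, cm = cost)
}

test_that("replicate weights are multinomial resamples of the site slots", {
  fix <- sim_fixture(6, 100, prob = 0.12, seed = 52)
  set.seed(52)
  reps <- make_replicates(fix$pa, 2000)
  expect_true(all(colSums(reps$W) == fix$pa$m))
  # mean weight of each pattern ~ d_i within 3 standard errors
  mw <- rowMeans(reps$W)
  se <- sqrt(fix$pa$weights * (1 - fix$pa$weights / fix$pa$m)) / sqrt(2000)
  expect_true(all(abs(mw - fix$pa$weights) <= 3 * se + 1e-9))
  set.seed(53); a <- make_replicates(fix$pa, 10)
  set.seed(53); b <- make_replicates(fix$pa, 10)
  expect_equal(a$W, b$W)
  expect_error(make_replicates(fix$pa, 0), "B must be")
})

test_that("offer_tree installs first trees, keeps incumbents on ties", {
  af <- armed_fixture()
  reps <- offer_tree(af$reps, af$t0, af$sc$scores)
  expect_true(all(is.finite(reps$best_score)))
  expect_true(all(vapply(reps$best_tree, Negate(is.null), logical(1L))))
  expect_equal(reps$best_score,
               as.numeric(colSums(reps$W * as.numeric(af$sc$scores))))
  # same tree again: strict improvement required, nothing changes
  reps2 <- offer_tree(reps, random_tree(6, af$t0$tip_label), af$sc$scores)
  expect_equal(reps2$best_score, reps$best_score)
  marks <- vapply(reps2$best_tree, function(x) topo_sig(x), character(1L))
  expect_equal(marks, vapply(reps$best_tree, topo_sig, character(1L)))
})

test_that("abort on/off give identical replicate outcomes over many offers", {
  af <- armed_fixture(seed = 54)
  reps_on <- af$reps
  reps_off <- af$reps
  set.seed(55)
  for (i in 1:40) {
    t <- random_stepwise_addition(af$fix$pa, af$cm)
    sc <- score_tree(t, af$fix$pa, af$cm)
    reps_on <- offer_tree(reps_on, t, sc$scores, use_abort = TRUE)
    reps_off <- offer_tree(reps_off, t, sc$scores, use_abort = FALSE)
  }
  expect_equal(reps_on$best_score, reps_off$best_score)
  expect_equal(vapply(reps_on$best_tree, topo_sig, character(1L)),
               vapply(reps_off$best_tree, topo_sig, character(1L)))
})

test_that("refinement never worsens and tracks exact rescoring", {
  af <- armed_fixture(seed = 56)
  reps <- offer_tree(af$reps, af$t0, af$sc$scores)
  before <- reps$best_score
  reps <- refine(reps, af$fix$pa, af$cm, radius = Inf)
  expect_true(all(reps$best_score <= before))
  for (b in seq_len(reps$B)) {
    sc <- score_tree(reps$best_tree[[b]], af$fix$pa, af$cm,
                     weights = reps$W[, b])
    expect_equal(sc$total, reps$best_score[b])
  }
  # refining again is a no-op (local optima are fixed points)
  again <- refine(reps, af$fix$pa, af$cm, radius = Inf)
  expect_equal(again$best_score, reps$best_score)
})

test_that("support mapping counts split frequencies exactly", {
  best <- parse_newick("((t1,t2),((t3,t4),(t5,t6)));")
  alt <- parse_newick("((t1,t3),((t2,t4),(t5,t6)));")
  reps <- structure(list(B = 4L,
                         best_tree = list(best, best, best, alt),
                         best_score = rep(0, 4)),
                    class = "bootstrap_replicates")
  st <- support_on_best_tree(best, reps)
  expect_equal(sort(unname(st$support[split_keys(best)])),
               sort(c(75, 75, 100)))
  # identical replicate trees give all-100 supports
  reps2 <- structure(list(B = 3L, best_tree = list(best, best, best)),
                     class = "bootstrap_replicates")
  st2 <- support_on_best_tree(best, reps2)
  expect_true(all(st2$support == 100))
  # invariance under taxon-order permutation of the replicate trees
  perm <- parse_newick("(((t6,t5),(t4,t3)),(t2,t1));")
  reps3 <- structure(list(B = 3L, best_tree = list(best, perm, best)),
                     class = "bootstrap_replicates")
  expect_true(all(support_on_best_tree(best, reps3)$support == 100))
})

test_that("majority consensus keeps splits above threshold, compatibly", {
  best <- parse_newick("((t1,t2),((t3,t4),(t5,t6)));")
  alt <- parse_newick("((t1,t3),((t2,t4),(t5,t6)));")
  reps <- structure(list(B = 3L, best_tree = list(best, best, alt)),
                    class = "bootstrap_replicates")
  cons <- majority_consensus(reps, best$tip_label)
  expect_true(all(cons$support > 50))
  expect_true(any(abs(cons$support - 200 / 3) < 1e-9)) # 2-of-3 splits kept
  # split sets of the output are pairwise compatible (it parses as a tree
  # and round-trips through ape)
  expect_s3_class(cons$tree, "phylo")
  expect_equal(sort(cons$tree$tip.label), sort(best$tip_label))
  # identical trees: consensus equals that topology, supports all 100
  reps2 <- structure(list(B = 3L, best_tree = list(best, best, best)),
                     class = "bootstrap_replicates")
  cons2 <- majority_consensus(reps2, best$tip_label)
  expect_setequal(cons2$splits, split_keys(best))
  expect_true(all(cons2$support == 100))
  back <- phylo_to_mptree(cons2$tree)
  expect_true(tree_equal(back, best))
  expect_error(majority_consensus(reps2, best$tip_label, threshold = 30),
               "threshold")
})

test_that("pairwise compatibility of consensus splits holds on random inputs", {
  set.seed(57)
  compatible <- function(a, b, n) {
    A <- as.integer(strsplit(a, ",")[[1]]); B <- as.integer(strsplit(b, ",")[[1]])
    !length(intersect(A, B)) || all(A %in% B) || all(B %in% A) ||
      length(union(A, B)) == n
  }
  for (rep in 1:5) {
    trees <- lapply(1:7, function(i) random_tree(8))
    reps <- structure(list(B = 7L, best_tree = trees),
                      class = "bootstrap_replicates")
    cons <- majority_consensus(reps, trees[[1]]$tip_label)
    expect_s3_class(cons$tree, "phylo")
    ks <- cons$splits
    if (length(ks) >= 2)
      for (i in 1:(length(ks) - 1)) for (j in (i + 1):length(ks))
        expect_true(compatible(ks[i], ks[j], 8L))
  }
})
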