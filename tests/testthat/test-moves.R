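test_that("the SPR neighborhood matches an independent reachability oracle", {
  # 4 tips: both alternative topologies are reached already at radius 1
  t4 <- parse_newick("((t1,t2),(t3,t4));")
  mv <- spr_neighbors(t4, radius = 2)
  sigs <- unique(vapply(seq_len(nrow(mv)), function(i)
    topo_sig(apply_spr(t4, mv[i, ])), character(1L)))
  others <- setdiff(vapply(all_topologies(4), topo_sig, character(1L)),
                    topo_sig(t4))
  expect_setequal(sigs, others)

  # 5 tips: neighborhood at unlimited radius equals the oracle's SPR ball
  set.seed(31)
  topos5 <- all_topologies(5)
  for (rep in 1:3) {
    t <- random_tree(5)
    mv <- spr_neighbors(t, radius = Inf)
    got <- unique(vapply(seq_len(nrow(mv)), function(i)
      topo_sig(apply_spr(t, mv[i, ])), character(1L)))
    want <- vapply(Filter(function(t2) oracle_spr_reachable(t, t2), topos5),
                   topo_sig, character(1L))
    expect_setequal(got, want)
    expect_false(topo_sig(t) %in% got)  # no move recreates the topology
  }
})

test_that("radius limits are monotone and moves invert cleanly", {
  set.seed(32)
  t <- random_tree(8)
  m1 <- spr_neighbors(t, radius = 1)
  m6 <- spr_neighbors(t, radius = 6)
  key <- function(m) apply(m[, 1:4, drop = FALSE], 1, paste, collapse = "-")
  expect_true(all(key(m1) %in% key(m6)))
  expect_true(all(m1[, "dist"] >= 1))
  # applying a move and the corresponding inverse restores the topology
  for (i in sample(nrow(m6), 10)) {
    t2 <- apply_spr(t, m6[i, ])
    validate_mptree(t2)
    p <- m6[[i, "p"]]; s <- m6[[i, "s"]]
    # p's former neighbours x,y were rejoined; the inverse regrafts there
    xy <- setdiff(t$nb[p, ], s)
    back <- apply_spr(t2, c(p = p, s = s, a = xy[1], b = xy[2]))
    expect_true(tree_equal(back, t))
  }
})

test_that("hill climbing descends to local optima deterministically", {
  set.seed(34)
  fix <- sim_fixture(6, 80, prob = 0.12)
  cm <- uniform_cost("dna")
  t0 <- random_tree(6)
  res <- hill_climb_spr(t0, fix$pa, cm, radius = Inf, collect = TRUE)
  expect_lte(res$total, res$start_total)
  tots <- vapply(res$visited, `[[`, numeric(1), "total")
  expect_true(all(diff(c(res$start_total, tots)) < 0)) # strict descent
  expect_equal(res$total, score_tree(res$tree, fix$pa, cm)$total)
  # a local optimum is a fixed point
  res2 <- hill_climb_spr(res$tree, fix$pa, cm, radius = Inf, collect = TRUE)
  expect_true(tree_equal(res2$tree, res$tree))
  expect_length(res2$visited, 0)
})

test_that("5-taxon basin analysis: climbs reach the global optimum as often as the oracle", {
  set.seed(35)
  fix <- sim_fixture(5, 60, prob = 0.15)
  cm <- uniform_cost("dna")
  topos <- all_topologies(5)
  exact <- vapply(topos, function(t) oracle_total(t, fix$pa, cm$cost),
                  numeric(1L))
  opt <- min(exact)
  # oracle climb: best-improvement over oracle-enumerated SPR neighborhoods
  sig2idx <- stats::setNames(seq_along(topos),
                             vapply(topos, topo_sig, character(1L)))
  nbhd <- lapply(topos, function(t)
    which(vapply(topos, function(t2) oracle_spr_reachable(t, t2),
                 logical(1L))))
  oracle_final <- vapply(seq_along(topos), function(i) {
    repeat {
      cand <- nbhd[[i]]
      best <- cand[which.min(exact[cand])]
      if (exact[best] >= exact[i]) return(exact[i])
      i <- best
    }
  }, numeric(1L))
  mine <- vapply(topos, function(t)
    hill_climb_spr(t, fix$pa, cm, radius = Inf)$total, numeric(1L))
  expect_equal(sort(mine), sort(oracle_final))
  expect_gte(sum(mine == opt), sum(oracle_final == opt))
})

test_that("stepwise addition is seeded, uniform without signal, exact with it", {
  # signal-free alignment: the three 4-taxon topologies score identically
  a <- aln_from_columns(c("AACC", "ACAC", "ACCA"))
  pa <- compress_informative(a)
  cm <- uniform_cost("dna")
  set.seed(36)
  sigs <- replicate(3000, topo_sig(random_stepwise_addition(pa, cm)))
  tab <- table(sigs)
  expect_equal(length(tab), 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)

  # perfect split signal is always recovered
  perfect <- compress_informative(aln_from_columns(rep("AACC", 3)))
  for (i in 1:20)
    expect_equal(topo_sig(random_stepwise_addition(perfect, cm)),
                 topo_sig(parse_newick("((t1,t2),(t3,t4));")))

  fix <- sim_fixture(7, 60, seed = 37)$pa
  set.seed(37); s1 <- random_stepwise_addition(fix, cm)
  set.seed(37); s2 <- random_stepwise_addition(fix, cm)
  expect_true(tree_equal(s1, s2))
})

test_that("NNI perturbation honours counts, enumeration and seeding", {
  t4 <- parse_newick("((t1,t2),(t3,t4));")
  set.seed(38)
  alt <- replicate(50, topo_sig(random_nni_perturb(t4, 0.5)))
  others <- setdiff(vapply(all_topologies(4), topo_sig, character(1L)),
                    topo_sig(t4))
  expect_setequal(unique(alt), others)   # one NNI, both alternatives occur

  # ceiling rule: n = 10 has 7 internal edges -> 4 NNIs
  expect_equal(ceiling(0.5 * 7), 4)
  t10 <- random_tree(10)
  p10 <- random_nni_perturb(t10, 0.5)
  validate_mptree(p10)
  # at most 4 splits can differ (each NNI rewrites one split)
  expect_lte(length(setdiff(split_keys(t10), split_keys(p10))), 4L)
  expect_gte(length(setdiff(split_keys(t10), split_keys(p10))), 1L)

  set.seed(39); a <- random_nni_perturb(t10, 0.5)
  set.seed(39); b <- random_nni_perturb(t10, 0.5)
  expect_true(tree_equal(a, b))
})
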