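test_that("chao1 follows the classic and bias-corrected branches", {
  expect_equal(chao1(c(1, 1, 2, 3)), 6)
  expect_equal(chao1(c(5, 5, 5)), 3)    # no singletons/doubletons
  expect_equal(chao1(c(1, 1)), 3)       # F2 = 0 branch
  expect_error(chao1(c(0, 0)), "all counts are zero")
  expect_error(chao1(c(1.5, 2)), "non-negative integers")
})

test_that("chao1 never falls below observed richness", {
  set.seed(1)
  for (i in 1:50) {
    v <- rpois(40, lambda = runif(1, 0.2, 3))
    if (sum(v) == 0) next
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("Good's coverage is 1 - F1/N with correct boundaries", {
  expect_equal(goods_coverage(c(1, 1, 3, 5)), 0.8)  # N = 10, two singletons
  expect_equal(goods_coverage(c(5, 5)), 1)
  expect_equal(goods_coverage(c(1, 1, 1, 1, 1)), 0)
  set.seed(2)
  for (i in 1:20) {
    v <- rpois(30, 1)
    if (sum(v) == 0) next
    g <- goods_coverage(v)
    expect_true(g >= 0 && g <= 1)
  }
})

test_that("Faith's PD spans the minimal rooted subtree", {
  tree <- four_leaf_tree()
  expect_equal(faith_pd(c(A = 3), tree), 2)                      # pendant + stem
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1, D = 2), tree), 6) # whole tree
  expect_equal(faith_pd(c(A = 0, B = 0), tree), 0)               # empty sample
  expect_error(faith_pd(c(E = 1), tree), "absent from the tree")
})

test_that("Faith's PD is monotone under adding taxa and bounded by total length", {
  set.seed(3)
  tree <- simulate_tree(15)
  total <- sum(tree$edge.length)
  for (i in 1:10) {
    sub <- sample(tree$tip.label, sample(1:10, 1))
    sup <- unique(c(sub, sample(tree$tip.label, 3)))
    pd_sub <- faith_pd(sub, tree)
    pd_sup <- faith_pd(sup, tree)
    expect_gte(pd_sup, pd_sub - 1e-12)
    expect_lte(pd_sup, total + 1e-12)
  }
})

test_that("alpha_diversity returns per-sample estimators consistent with the scalar forms", {
  set.seed(4)
  tbl <- toy_table(matrix(rpois(5 * 40, 2), nrow = 5))
  a <- alpha_diversity(tbl)
  expect_equal(nrow(a), 5)
  expect_equal(a$chao1[3], chao1(as.numeric(tbl[3, -1])))
  expect_equal(a$goods_coverage[2], goods_coverage(as.numeric(tbl[2, -1])))
  expect_true(all(a$chao1 >= a$s_obs))
  expect_true(all(a$goods_coverage >= 0 & a$goods_coverage <= 1))
})

test_that("rarefy hits the target depth exactly and is reproducible by seed", {
  set.seed(5)
  tbl <- toy_table(matrix(rpois(4 * 50, 10), nrow = 4))
  r1 <- rarefy(tbl, 100, seed = 9)
  expect_true(all(rowSums(r1[, -1]) == 100))
  expect_true(all(as.matrix(r1[, -1]) <= as.matrix(tbl[, -1])))
  r2 <- rarefy(tbl, 100, seed = 9)
  expect_identical(r1, r2)
  # depth equal to a sample's total returns it unchanged
  tot <- sum(tbl[1, -1])
  r3 <- rarefy(tbl[1, ], tot, seed = 1)
  expect_equal(as.numeric(r3[1, -1]), as.numeric(tbl[1, -1]))
  expect_error(rarefy(tbl, 0), "positive integer")
})

test_that("rarefy drops and names samples below the requested depth", {
  tbl <- toy_table(rbind(c(1000, 1000), c(3, 2)))
  expect_warning(r <- rarefy(tbl, 100), "S2")
  expect_equal(r$sample_id, "S1")
})

test_that("rarefaction subsampling matches the hypergeometric expectation", {
  tbl <- toy_table(rbind(c(1000, 1000)))
  draws <- vapply(1:300, function(s) as.numeric(rarefy(tbl, 1000, seed = s)[[2]]),
                  numeric(1))
  # single draw sd from the hypergeometric; compare the mean of 300 draws
  hyper_sd <- sqrt(1000 * 0.5 * 0.5 * (2000 - 1000) / (2000 - 1))
  se <- hyper_sd / sqrt(300)
  expect_lt(abs(mean(draws) - 500), 3 * se)
})

test_that("rarefaction curves are anchored at 0 and S_obs and near-monotone", {
  set.seed(6)
  tbl <- toy_table(matrix(rpois(2 * 30, 4), nrow = 2))
  tot <- min(rowSums(tbl[, -1]))
  rc <- rarefaction_curves(tbl, depths = c(0, 5, 20, tot), replicates = 10, seed = 2)
  expect_true(all(rc$mean_otus[rc$depth == 0] == 0))
  full <- rc[rc$depth == tot & rc$sample_id == "S1", ]
  if (nrow(full) == 1 && sum(tbl[1, -1]) == tot) {
    expect_equal(full$mean_otus, sum(tbl[1, -1] > 0))
  }
  for (s in unique(rc$sample_id)) {
    m <- rc$mean_otus[rc$sample_id == s][order(rc$depth[rc$sample_id == s])]
    expect_true(all(diff(m) > -1.5)) # Monte-Carlo tolerance
  }
  # a single read always reveals exactly one OTU
  rc1 <- rarefaction_curves(toy_table(rbind(c(50, 50))), depths = 1,
                            replicates = 20, seed = 3)
  expect_equal(rc1$mean_otus, 1)
})
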