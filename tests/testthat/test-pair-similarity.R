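# Distance matrix with prescribed male-female entries for n pairs.
dist_fixture <- function(mf, meta) {
  ids <- meta$sample_id
  m <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  pairs <- unique(meta$pair_id)
  for (k in seq_along(pairs)) {
    male <- meta$sample_id[meta$pair_id == pairs[k] & meta$sex == "M"]
    female <- meta$sample_id[meta$pair_id == pairs[k] & meta$sex == "F"]
    m[male, female] <- m[female, male] <- mf[k]
  }
  m
}

test_that("mean within-pair distance averages the male-female entries", {
  meta <- toy_metadata(2)
  m <- dist_fixture(c(0.2, 0.4), meta)
  expect_equal(mean_within_pair_distance(m, meta), 0.3)
  expect_equal(mean_within_pair_distance(dist_fixture(c(0.3, 0.3), meta), meta), 0.3)
  # order of rows in the matrix is irrelevant
  perm <- sample(rownames(m))
  expect_equal(mean_within_pair_distance(m[perm, perm], meta), 0.3)
  # incomplete pair is an error naming the pair
  expect_error(mean_within_pair_distance(m, meta[-1, ]), "P1")
})

test_that("sample-centred test is calibrated on an exchangeable configuration", {
  meta <- toy_metadata(7)
  m <- dist_fixture(rep(0.5, 7), meta) # every male-female distance equal
  res <- sample_centred_test(m, meta, B = 500, seed = 1)
  expect_equal(res$p_lower, 1)
  expect_equal(res$p_upper, 1)
  expect_equal(res$observed, res$null_mean)
  expect_equal(res$null_sd, 0)
})

test_that("sample-centred test detects within-pair distances smaller than any re-pairing", {
  meta <- toy_metadata(7)
  m <- dist_fixture(rep(0.01, 7), meta) # the 7 smallest of all 49 cross distances
  res <- sample_centred_test(m, meta, B = 1000, seed = 2)
  expect_lte(res$p_lower, 0.01)
  expect_lt(res$ses, 0)
  expect_equal(res$p_two_tailed, min(1, 2 * min(res$p_lower, res$p_upper)))
  # add-one convention: no null mean at or below the observed except possibly
  # the identity bijection itself
  expect_gte(res$p_lower, 1 / 1001)
})

test_that("permutation p-values respect the add-one convention bounds", {
  meta <- toy_metadata(4)
  set.seed(3)
  m <- dist_fixture(runif(4), meta)
  res <- sample_centred_test(m, meta, B = 200, seed = 4)
  for (p in c(res$p_lower, res$p_upper, res$p_two_tailed)) {
    expect_gte(p, 1 / 201)
    expect_lte(p, 1)
  }
  expect_equal(res$ses, (res$observed - res$null_mean) / res$null_sd)
})

test_that("per-OTU correlation profile handles monotone, reversed and constant patterns", {
  meta <- toy_metadata(3)
  prop <- toy_table(rbind(
    c(1, 30, 0), c(2, 10, 50),
    c(2, 20, 0), c(4, 20, 50),
    c(3, 10, 0), c(6, 30, 50)
  ), sample_ids = meta$sample_id, otu_ids = c("up", "down", "flat")) |>
    relative_abundance()
  pr <- pair_correlation_profile(prop, meta, otu_subset = c("up", "down", "flat"))
  expect_equal(pr$r[pr$otu_id == "up"], 1)
  expect_equal(pr$r[pr$otu_id == "down"], -1)
  expect_true(is.na(pr$r[pr$otu_id == "flat"]))
  expect_equal(pr$n_pairs_used, rep(3L, 3))
  # Fisher z of a clamped perfect correlation is finite
  expect_equal(pr$fisher_z[pr$otu_id == "up"], atanh(1 - 1e-12))
})

test_that("OTU-centred test reaches the minimal p on perfectly copied profiles", {
  meta <- toy_metadata(7)
  set.seed(13)
  base <- matrix(rpois(7 * 25, 20), nrow = 7) # one count profile per pair
  prop <- toy_table(base[rep(1:7, each = 2), ], sample_ids = meta$sample_id) |>
    relative_abundance()
  res <- otu_centred_test(prop, meta, B = 200, seed = 5)
  expect_equal(res$p_upper, 1 / 201)
  expect_gt(res$ses, 3)
  expect_equal(res$observed, atanh(1 - 1e-12), tolerance = 1e-6)
})

test_that("the OTU-centred statistic drops undefined OTUs consistently and reports them", {
  meta <- toy_metadata(4)
  set.seed(14)
  counts <- matrix(rpois(8 * 20, 3), nrow = 8)
  counts[, 1] <- 5 # constant across everyone -> constant proportions? not quite
  counts[, 2] <- 0 # all-zero OTU -> constant in both sexes
  counts[1, 1] <- 5
  tbl <- toy_table(counts, sample_ids = meta$sample_id)
  prop <- relative_abundance(tbl)
  res <- otu_centred_test(prop, meta, B = 99, seed = 6)
  expect_gte(res$n_undefined, 1)
  expect_equal(res$n_units + res$n_undefined, 20L)
  pr <- pair_correlation_profile(prop, meta)
  expect_equal(sum(is.na(pr$r)), res$n_undefined)
})

test_that("standardised effect size follows (observed - null mean) / null sd", {
  res <- micropair:::new_pair_perm_test("x", observed = 0.3,
                                        null = c(0, 0.1, 0.2), B = 3,
                                        seed = NULL, n_units = 1)
  expect_equal(res$null_mean, 0.1)
  expect_equal(res$null_sd, 0.1)
  expect_equal(res$ses, 2)
})

test_that("OTU-centred test results are invariant to sample and OTU order", {
  sim <- simulate_paired_community(n_otus = 60, rho = 0.4, seed = 31)
  prop <- relative_abundance(sim$table)
  sub <- setdiff(names(filter_otus(sim$table, 4, 0)), "sample_id")
  a <- otu_centred_test(prop, sim$metadata, sub, B = 99, seed = 7)
  set.seed(15)
  prop2 <- prop[sample(nrow(prop)), c("sample_id", sample(setdiff(names(prop), "sample_id")))]
  meta2 <- sim$metadata[sample(nrow(sim$metadata)), ]
  b <- otu_centred_test(prop2, meta2, sub, B = 99, seed = 7)
  expect_equal(b$observed, a$observed)
  expect_equal(b$null, a$null)
  expect_equal(b$p_upper, a$p_upper)
})

test_that("the OTU-centred test applied to its own null is uniformly calibrated", {
  p <- vapply(1:100, function(i) {
    sim <- simulate_paired_community(n_otus = 80, rho = 0, seed = 40000 + i)
    prop <- relative_abundance(sim$table)
    sub <- setdiff(names(filter_otus(sim$table, 4, 0.001)), "sample_id")
    otu_centred_test(prop, sim$metadata, sub, B = 99, seed = 41000 + i)$p_upper
  }, numeric(1))
  # binomial 99.9% envelopes around the nominal levels
  for (alpha in c(0.1, 0.25, 0.5)) {
    hits <- sum(p <= alpha)
    expect_gte(hits, qbinom(0.0005, 100, alpha))
    expect_lte(hits, qbinom(0.9995, 100, alpha))
  }
})

test_that("label exclusion preserves order and warns about stray ids", {
  expect_equal(exclude_otus_by_label(c("a", "b", "c"), "b"), c("a", "c"))
  expect_equal(exclude_otus_by_label(c("a", "b"), character(0)), c("a", "b"))
  expect_warning(out <- exclude_otus_by_label(c("a", "b"), "z"), "not present")
  expect_equal(out, c("a", "b"))
})

test_that("tidy and glance summarise a permutation test as one-row tibbles", {
  meta <- toy_metadata(4)
  set.seed(16)
  m <- dist_fixture(runif(4), meta)
  res <- sample_centred_test(m, meta, B = 99, seed = 8)
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, res$observed)
  expect_equal(td$p.value, res$p_two_tailed)
  gl <- glance(res)
  expect_equal(gl$n_permutations, 99L)
  expect_equal(gl$seed, 8L)
})
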