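test_that("single-run RFE puts an informative feature above pure noise", {
  set.seed(61)
  hits <- replicate(60, {
    y <- rep(c(-1, 1), each = 20)
    X <- cbind(info = y + rnorm(40, sd = 0.3), noise = rnorm(40))
    svm_rfe_single(X, y)[1] == 1L
  })
  expect_gte(mean(hits), 0.95)
})

test_that("RFE handles degenerate feature sets and tie-breaks by column index", {
  y <- rep(c(-1, 1), each = 10)
  x1 <- matrix(y + rnorm(20, sd = 0.1), ncol = 1)
  expect_equal(svm_rfe_single(x1, y), 1L)
  # exact duplicate columns score identically, so the tie rule eliminates
  # the lower column index first (worse rank); once one duplicate is gone
  # the survivor carries the information and is ranked first
  set.seed(62)
  info <- y + rnorm(20, sd = 0.1)
  X <- cbind(info, info, rnorm(20))
  rk <- svm_rfe_single(X, y)
  pos1 <- which(rk == 1L); pos2 <- which(rk == 2L)
  expect_gt(pos1, pos2)
  expect_equal(rk[1], 2L)
  expect_error(svm_rfe_single(X, rep(1, 20)), "both classes")
})

test_that("positional vote counting follows the most-common-so-far rule", {
  # feature 2 wins rank 1 with 600 first-place votes vs 400
  rank_mat <- rbind(
    matrix(rep(c(2L, 1L, 3L), 600), ncol = 3, byrow = TRUE),
    matrix(rep(c(1L, 3L, 2L), 400), ncol = 3, byrow = TRUE))
  cons <- consensus_from_rankings(rank_mat)
  expect_equal(cons$column, c(2L, 1L, 3L))
  expect_equal(cons$votes[1], 600L)
  # rank-2 winner counts appearances over columns 1-2: feature 1 has
  # 600 + 400 = 1000
  expect_equal(cons$votes[2], 1000L)
  # vote ties break toward the lower feature index
  tie <- rbind(c(1L, 2L), c(2L, 1L))
  expect_equal(consensus_from_rankings(tie)$column, c(1L, 2L))
})

test_that("consensus with one full-sample run equals the single ranking and is a permutation", {
  set.seed(63)
  y <- rep(c(-1, 1), each = 12)
  X <- cbind(y + rnorm(24, sd = 0.5), matrix(rnorm(24 * 5), 24))
  single <- svm_rfe_single(X, y)
  cons <- consensus_rank(X, y, n_runs = 1L, subsample = 1, seed = 7)
  expect_equal(cons$column, single)
  cons10 <- consensus_rank(X, y, n_runs = 10L, subsample = 0.9, seed = 7)
  expect_setequal(cons10$column, seq_len(ncol(X)))
  # deterministic under the same seed
  cons10b <- consensus_rank(X, y, n_runs = 10L, subsample = 0.9, seed = 7)
  expect_equal(cons10$column, cons10b$column)
  expect_error(consensus_rank(X[c(1, 13), ], y[c(1, 13)], subsample = 0.9),
               "fewer than 2")
})

test_that("feature tables and top-k annotation work end to end on a small cohort", {
  m <- tiny_montage()
  cfg <- tiny_config(seed = 64, n_subjects = 8L, duration_s = 20)
  coh <- generate_cohort(cfg, m)
  sc <- cohort_mean_connectivity(coh, eeg_bands()["beta"], window_spec(4, 2))
  conds <- coh$manifest$condition
  es <- select_significant_edges(sc, conds, alpha = 0.05, mont = m)
  expect_gt(nrow(es$beta), 0L)
  ft <- feature_table(sc, conds, es, m)
  expect_equal(nrow(ft$X), 16L)
  expect_equal(ncol(ft$X), nrow(es$beta))
  expect_setequal(unique(ft$y), c(-1, 1))
  rk <- consensus_rank(ft, n_runs = 10L, seed = 65)
  # the planted F3-P3 edge (coupling 0.1 vs 0.9) should rank near the top
  planted_col <- which(ft$features$channel_a == "F3" &
                         ft$features$channel_b == "P3")
  expect_length(planted_col, 1L)
  expect_lte(which(rk$column == planted_col), 3L)
  top <- top_k(rk, 2L, m)
  expect_equal(nrow(top), 2L)
  expect_true(all(c("region_category", "direction") %in% names(top)))
  planted_row <- top[top$channel_a == "F3" & top$channel_b == "P3", ]
  if (nrow(planted_row)) {
    expect_equal(planted_row$region_category, "frontal-parietal")
    expect_equal(planted_row$direction, "B > A")
  }
  expect_equal(nrow(top_k(rk, 0L, m)), 0L)
  expect_error(top_k(rk, nrow(rk) + 1L, m), "available")
})
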