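test_that("one-way ANOVA reproduces hand-computed and degenerate cases", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_equal(unname(a$df), c(1, 4))
  expect_equal(a$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  same <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_true(isTRUE(attr(same, "degenerate")))
  expect_error(anova_oneway(list(1:3)), "2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "2 values")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(51)
  for (rep in 1:20) {
    g1 <- rnorm(sample(5:15, 1)); g2 <- rnorm(sample(5:15, 1), mean = 0.3)
    f <- anova_oneway(list(g1, g2))$F
    t <- stats::t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("null p values are uniform", {
  set.seed(52)
  ps <- replicate(2000, anova_oneway(list(rnorm(8), rnorm(8),
                                          rnorm(8)))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("network feature comparison yields one row per band x metric", {
  set.seed(53)
  grid <- expand.grid(subject = 1:8, condition = c("A", "B"),
                      band = c("delta", "theta", "alpha", "beta"),
                      metric = c("Lw", "Cw", "Eglobal", "Elocal"),
                      stringsAsFactors = FALSE)
  grid$auc <- rnorm(nrow(grid))
  # plant a strong beta/Lw difference
  sel <- grid$band == "beta" & grid$metric == "Lw" & grid$condition == "B"
  grid$auc[sel] <- grid$auc[sel] + 10
  cmp <- compare_network_features(grid)
  expect_equal(nrow(cmp), 16L)
  hit <- cmp[cmp$band == "beta" & cmp$metric == "Lw", ]
  expect_true(hit$significant)
  expect_gt(hit$mean_B, hit$mean_A)
  # mismatched subject sets are rejected
  bad <- grid[!(grid$subject == 1 & grid$condition == "A"), ]
  expect_error(compare_network_features(bad), "subject")
})

make_fake_conn <- function(n_per_cond, mont, edge_delta = NULL,
                           seed = 1) {
  # window-averaged PLI stand-ins: null edges ~ N(0.1, 0.01), the planted
  # edge shifted in condition B
  set.seed(seed)
  n <- nrow(mont)
  ids <- c(paste0("S", 1:n_per_cond, "_A"), paste0("S", 1:n_per_cond, "_B"))
  conds <- rep(c("A", "B"), each = n_per_cond)
  conn <- lapply(seq_along(ids), function(k) {
    m <- rand_sym(n) * 0.01 + 0.1
    if (!is.null(edge_delta) && conds[k] == "B")
      m[edge_delta[1], edge_delta[2]] <- m[edge_delta[2], edge_delta[1]] <-
        m[edge_delta[1], edge_delta[2]] + 0.5
    list(beta = m)
  })
  names(conn) <- ids
  list(conn = conn, conds = conds)
}

test_that("edge selection keeps planted contrasts and respects alpha", {
  m <- tiny_montage()
  fake <- make_fake_conn(10, m, edge_delta = c(2, 6), seed = 54)
  es <- select_significant_edges(fake$conn, fake$conds, alpha = 0.05,
                                 mont = m)
  expect_true(all(es$beta$p < 0.05))
  target <- edge_index(2, 6, 8)
  expect_true(target %in% es$beta$edge)
  expect_equal(es$beta$edge[1], target)  # smallest p first
  # alpha = 0 selects nothing
  es0 <- select_significant_edges(fake$conn, fake$conds, alpha = 0,
                                  mont = m)
  expect_equal(nrow(es0$beta), 0L)
  # null data: selection stays near the nominal rate
  null <- make_fake_conn(10, m, seed = 55)
  esn <- select_significant_edges(null$conn, null$conds, alpha = 0.05,
                                  mont = m)
  expect_lt(nrow(esn$beta), 0.25 * 28)
  # FDR correction prunes null selections
  esf <- select_significant_edges(null$conn, null$conds, alpha = 0.05,
                                  mont = m, fdr = TRUE)
  expect_lte(nrow(esf$beta), nrow(esn$beta))
})
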