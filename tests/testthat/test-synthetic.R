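test_that("generated recordings have the configured shape and are seed-deterministic", {
  cfg <- tiny_config(seed = 21)
  m <- tiny_montage()
  r1 <- generate_subject(cfg, "A", 1, m)
  expect_equal(dim(r1$data), c(8, 12 * 200))
  expect_equal(r1$labels, m$label)
  r1b <- generate_subject(cfg, "A", 1, m)
  expect_identical(r1$data, r1b$data)
  # different subject, condition or master seed all change the data
  expect_false(identical(r1$data,
                         generate_subject(cfg, "A", 2, m)$data))
  expect_false(identical(r1$data,
                         generate_subject(cfg, "B", 1, m)$data))
  cfg2 <- tiny_config(seed = 22)
  expect_false(identical(r1$data,
                         generate_subject(cfg2, "A", 1, m)$data))
})

test_that("cohorts contain n_subjects recordings per condition and reproduce exactly", {
  cfg <- tiny_config(seed = 23, n_subjects = 3L, duration_s = 4)
  m <- tiny_montage()
  coh <- generate_cohort(cfg, m)
  expect_length(coh$recordings, 6L)
  expect_equal(as.vector(table(coh$manifest$condition)), c(3L, 3L))
  coh2 <- generate_cohort(cfg, m)
  expect_identical(coh$recordings[["S02_B"]]$data,
                   coh2$recordings[["S02_B"]]$data)
})

test_that("planted truth lists exactly the edges with differing coupling", {
  base <- eeg_bands()
  cfg <- synthetic_config(
    n_subjects = 2, duration_s = 4, fs = 200, bands = base,
    planted_edges = list(
      planted_edge("beta", "F3", "P3", 0.2, 0.8),
      planted_edge("beta", "Fp1", "O1", 0.5, 0.5),
      planted_edge("theta", "C3", "P3", 0, 1)))
  truth <- planted_truth(cfg)
  expect_equal(nrow(truth$beta), 1L)
  expect_equal(unname(truth$beta[1, ]), c("F3", "P3"))
  expect_equal(nrow(truth$theta), 1L)
  expect_equal(nrow(truth$alpha), 0L)
  empty <- synthetic_config(n_subjects = 2, duration_s = 4, fs = 200)
  expect_true(all(vapply(planted_truth(empty), nrow, integer(1)) == 0L))
  expect_error(planted_edge("beta", "F3", "P3", -0.1, 0.5), "0, 1")
  expect_error(synthetic_config(duration_s = 1.001, fs = 33), "whole")
})

# Shared helper: mean planted-pair PLI in one band at a given coupling.
planted_pair_pli <- function(coupling, band = "beta", n_sub = 5,
                             seed = 31) {
  m <- tiny_montage()
  cfg <- synthetic_config(
    n_subjects = n_sub, duration_s = 20, fs = 200,
    bands = eeg_bands()[c("delta", "beta")],
    planted_edges = list(planted_edge("beta", "F3", "P3",
                                      coupling, coupling)),
    subject_jitter_sd = 0, seed = seed)
  ij <- match(c("F3", "P3"), m$label)
  mean(vapply(seq_len(n_sub), function(s) {
    rec <- generate_subject(cfg, "A", s, m)
    rb <- bandpass_zero_phase(rec, eeg_bands()[[band]])
    mean_connectivity(window_pli_matrices(rb, window_spec(4, 2)))[ij[1], ij[2]]
  }, numeric(1)))
}

test_that("planted-pair PLI rises monotonically with coupling and saturates near 1", {
  plis <- vapply(c(0, 0.25, 0.5, 0.75, 1), planted_pair_pli, numeric(1))
  expect_true(all(diff(plis) > 0))
  expect_gt(plis[5], 0.8)   # full coupling, pi/4 lag
  expect_lt(plis[1], 0.15)  # uncoupled pair sits at the null level
})

test_that("coupling planted in beta does not leak into the delta band", {
  beta_on <- planted_pair_pli(1, band = "beta", seed = 33)
  delta_level <- planted_pair_pli(1, band = "delta", seed = 33)
  # null distribution of windowed delta PLI on uncoupled channels
  null_level <- planted_pair_pli(0, band = "delta", seed = 34)
  expect_gt(beta_on, 0.8)
  expect_lt(delta_level, max(0.25, 2 * null_level))
})
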