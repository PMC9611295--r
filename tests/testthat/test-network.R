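test_that("proportional threshold keeps exactly the strongest edges", {
  set.seed(41)
  # 4-node matrix with 6 distinct weights: keep top 3
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.9, 0.1, 0.5, 0.8, 0.3, 0.7)
  w <- w + t(w)
  net <- proportional_threshold(w, 0.5)
  kept <- sort(net[upper.tri(net)][net[upper.tri(net)] > 0],
               decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))
  # sort oracle on a random 60-node matrix at 15%
  m60 <- rand_sym(60)
  n15 <- proportional_threshold(m60, 0.15)
  expect_equal(sum(n15[upper.tri(n15)] > 0), 266L)  # round(0.15 * 1770)
  expect_equal(sort(n15[upper.tri(n15)][n15[upper.tri(n15)] > 0]),
               sort(m60[upper.tri(m60)], decreasing = TRUE)[266:1])
  # sparsity 1 keeps everything
  expect_equal(unclass(proportional_threshold(m60, 1))[, ], m60,
               ignore_attr = TRUE)
  expect_error(proportional_threshold(m60, 0), "sparsity")
  expect_error(proportional_threshold(matrix(1:9, 3, 3), 0.5), "symmetric")
})

test_that("threshold ties at the cutoff resolve to the smaller edge index", {
  w <- matrix(0, 3, 3)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5)   # edges (1,2), (1,3), (2,3)
  w <- w + t(w)
  net <- proportional_threshold(w, 1 / 3)  # keep exactly one edge
  expect_equal(net[1, 2], 0.5)
  expect_equal(net[1, 3] + net[2, 3], 0)
})

test_that("hand-computed metric values are reproduced", {
  # 3-node path with unit weights
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  d <- weighted_shortest_paths(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)
  # unit triangle
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(as.numeric(characteristic_path_length(tri)), 1)
  expect_equal(weighted_clustering(tri), 1)
  expect_equal(global_efficiency(tri), 1)
  expect_equal(local_efficiency(tri), 1)
  # triangle with weights (1, 0.5, 0.5)
  tri2 <- matrix(0, 3, 3)
  tri2[1, 2] <- tri2[2, 1] <- 1
  tri2[1, 3] <- tri2[3, 1] <- 0.5
  tri2[2, 3] <- tri2[3, 2] <- 0.5
  expect_equal(weighted_clustering(tri2), 0.25^(1 / 3))
  # complete graph at weight 0.5: every path has length 2
  comp <- 0.5 * (matrix(1, 4, 4) - diag(4))
  expect_equal(as.numeric(characteristic_path_length(comp)), 2)
  # star graph: no triangles, empty neighbour subgraphs
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(weighted_clustering(star), 0)
  expect_equal(local_efficiency(star), 0)
  # disconnection handling
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 1
  expect_true(all(!is.finite(weighted_shortest_paths(two)[1, 3:4])))
  lw <- characteristic_path_length(two)
  expect_true(attr(lw, "disconnected"))
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
})

test_that("all four metrics match brute-force oracles on random small graphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    w <- rand_sym(n, density = runif(1, 0.4, 1))
    expect_equal(as.numeric(characteristic_path_length(w)),
                 bf_char_path_length(w), tolerance = 1e-10)
    expect_equal(weighted_clustering(w), bf_clustering(w),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(w), bf_global_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(local_efficiency(w), bf_local_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("metrics scale as expected and respect path monotonicity", {
  set.seed(43)
  w <- rand_sym(7, density = 0.9)
  lam <- 2.5
  expect_equal(as.numeric(characteristic_path_length(lam * w)),
               as.numeric(characteristic_path_length(w)) / lam)
  expect_equal(global_efficiency(lam * w), lam * global_efficiency(w))
  expect_equal(weighted_clustering(lam * w),
               lam * weighted_clustering(w))
  # Jensen: mean of reciprocals >= reciprocal of mean on connected graphs
  for (rep in 1:10) {
    g <- rand_sym(6, density = 1)
    expect_gte(global_efficiency(g) + 1e-12,
               1 / as.numeric(characteristic_path_length(g)))
  }
  # adding an edge never lengthens any shortest path
  w2 <- w
  zeros <- which(w2 == 0 & row(w2) < col(w2), arr.ind = TRUE)
  if (nrow(zeros)) {
    w2[zeros[1, 1], zeros[1, 2]] <- w2[zeros[1, 2], zeros[1, 1]] <- 0.5
    expect_true(all(weighted_shortest_paths(w2) <=
                      weighted_shortest_paths(w) + 1e-12))
  }
})

test_that("the sparsity sweep covers the default grid and AUC obeys trapezoid identities", {
  grid <- default_sparsity_grid()
  expect_length(grid, 16L)
  set.seed(44)
  prof <- sparsity_sweep(rand_sym(12), grid)
  expect_equal(nrow(prof$profile), 16L)
  expect_named(prof$auc, c("Lw", "Cw", "Eglobal", "Elocal"))
  expect_true(all(is.finite(prof$profile$Eglobal)))
  # all-equal weights: thresholding keeps k edges but Cw is flat in weight
  expect_equal(auc_over_sparsity(rep(3, 16), grid), 0.15 * 3)
  expect_equal(auc_over_sparsity(seq(0, 1, length.out = 16), grid), 0.075)
  expect_equal(auc_over_sparsity(c(2, 4), c(0.15, 0.16)),
               0.01 * (2 + 4) / 2)
  expect_error(auc_over_sparsity(1, 0.15), "2 grid points")
  expect_error(sparsity_sweep(rand_sym(5), c(0.3, 0.2)), "ascending")
})
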