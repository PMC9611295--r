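# Small fixtures and independent brute-force oracles used across tests.

# Compact 8-channel montage covering all five regions; fast stand-in for
# the 60-channel default wherever channel count is irrelevant.
tiny_montage <- function(n = 8L) {
  labels <- c("Fp1", "F3", "FC1", "C3", "T7", "P3", "PO3", "O1")
  regions <- c("frontal", "frontal", "central", "central", "temporal",
               "parietal", "occipital", "occipital")
  montage(labels[seq_len(n)], regions[seq_len(n)])
}

# Random symmetric connectivity-like matrix, weights in (0, 1).
rand_sym <- function(n, density = 1) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  v <- runif(sum(up))
  v[runif(length(v)) > density] <- 0
  w[up] <- v
  w + t(w)
}

# --- brute-force graph oracles (independent of the package internals) ---

# All-pairs shortest paths on reciprocal weights via Floyd-Warshall.
bf_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_char_path_length <- function(w) {
  d <- bf_shortest_paths(w)
  if (any(!is.finite(d))) {
    # restrict to the largest connected component
    reach <- is.finite(d)
    comp <- rep(NA_integer_, nrow(w))
    cid <- 0L
    for (i in seq_len(nrow(w))) {
      if (is.na(comp[i])) {
        cid <- cid + 1L
        comp[reach[i, ]] <- cid
      }
    }
    keep <- which(comp == which.max(tabulate(comp)))
    d <- d[keep, keep, drop = FALSE]
  }
  n <- nrow(d)
  if (n < 2L) return(Inf)
  sum(d[row(d) != col(d)]) / (n * (n - 1L))
}

bf_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    t_i <- 0
    for (j in seq_len(n))
      for (h in seq_len(n))
        if (j != i && h != i && j != h)
          t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    t_i <- t_i / 2
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

bf_global_efficiency <- function(w) {
  d <- bf_shortest_paths(w)
  n <- nrow(w)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1L))
}

bf_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    dsub <- bf_shortest_paths(w[nb, nb, drop = FALSE])
    acc <- 0
    for (a in seq_len(k))
      for (b in seq_len(k))
        if (a != b && is.finite(dsub[a, b]))
          acc <- acc + (w[i, nb[a]] * w[i, nb[b]] / dsub[a, b])^(1 / 3)
    vals[i] <- acc / (k * (k - 1L))
  }
  mean(vals)
}

# Small two-band synthetic config on the tiny montage for pipeline-level
# tests: cheap but runs every stage.
tiny_config <- function(seed = 5L, n_subjects = 4L, duration_s = 12,
                        coupling_a = 0.1, coupling_b = 0.9) {
  synthetic_config(
    n_subjects = n_subjects, duration_s = duration_s, fs = 200,
    bands = eeg_bands()[c("theta", "beta")],
    planted_edges = list(planted_edge("beta", "F3", "P3",
                                      coupling_a, coupling_b)),
    subject_jitter_sd = 0.05, seed = seed)
}
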