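#' Build the feature table of significant edges
#'
#' One row per recording, one column per significant (band, edge) pair;
#' cell values are the recording's window-averaged PLI on that edge.
#' Class labels are coded -1 / +1 in sorted condition order.
#'
#' @param subject_conn named list (by recording id) of per-band lists of
#'   window-averaged connectivity matrices.
#' @param conditions condition label per recording (exactly two distinct).
#' @param edge_sets named list per band of significant-edge data.frames as
#'   returned by [select_significant_edges()]; bands with zero edges are
#'   skipped.
#' @param mont the [montage].
#' @return An object of class `feature_table`: list with `X` (numeric
#'   matrix), `y` (-1/+1), `conditions` (labels per row) and `features`
#'   (data.frame: band, edge, channel_a, channel_b).
#' @export
feature_table <- function(subject_conn, conditions, edge_sets,
                          mont = default_montage()) {
  conds <- sort(unique(conditions))
  if (length(conds) != 2L) stop("feature table needs exactly 2 conditions")
  n <- nrow(mont)
  pairs <- edge_pairs(n)
  feats <- do.call(rbind, lapply(names(edge_sets), function(b) {
    es <- edge_sets[[b]]
    if (!nrow(es)) return(NULL)
    data.frame(band = b, edge = es$edge, channel_a = es$channel_a,
               channel_b = es$channel_b)
  }))
  if (is.null(feats) || !nrow(feats))
    stop("no significant edges in any band")
  X <- vapply(subject_conn, function(sc)
    vapply(seq_len(nrow(feats)), function(r)
      sc[[feats$band[r]]][pairs[feats$edge[r], , drop = FALSE]],
      numeric(1L)),
    numeric(nrow(feats)))
  X <- t(X)
  colnames(X) <- paste0(feats$band, ":", feats$channel_a, "-",
                        feats$channel_b)
  y <- ifelse(conditions == conds[2L], 1, -1)
  structure(list(X = X, y = y, conditions = conditions, features = feats),
            class = "feature_table")
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
}

rbf_kernel <- function(A, gamma) {
  d2 <- as.matrix(stats::dist(A))^2
  exp(-gamma * d2)
}

#' Single-run SVM recursive feature elimination
#'
#' Backward elimination: train the SVM on the remaining features, score
#' every feature by how much its removal would change the margin
#' objective, drop the lowest-scoring feature, retrain, and repeat until
#' all features are ranked. The returned order reverses elimination, so
#' rank 1 is the last survivor (most informative feature).
#'
#' With the default RBF kernel the removal score of feature j is the
#' kernel-RFE criterion `(W2(a) - W2_(-j)(a)) / 2`, where
#' `W2(a) = sum_ab a_a a_b y_a y_b K(x_a, x_b)` and `K` is recomputed with
#' feature j struck out while the support-vector multipliers are held
#' fixed. The score is kept signed: for a linear kernel it reduces exactly
#' to `w_j^2 / 2 >= 0`, whereas under an RBF kernel removing an
#' uninformative feature inflates all kernel similarities and scores
#' negative, so such features are eliminated first. With
#' `kernel = "linear"` the score is the squared weight-vector component
#' `w_j^2`. Ties are broken toward the lower column index. Columns are
#' standardised to zero mean and unit variance before ranking.
#'
#' @param X numeric matrix (rows = samples) or a [feature_table].
#' @param y class labels in `{-1, +1}` (ignored if `X` is a feature
#'   table); both classes must be present.
#' @param C SVM cost parameter.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width; default `1 / n_remaining_features` on
#'   standardised columns.
#' @return Integer vector of column indices, best feature first.
#' @export
svm_rfe_single <- function(X, y = NULL, C = 1, kernel = c("rbf", "linear"),
                           gamma = NULL) {
  if (inherits(X, "feature_table")) { y <- X$y; X <- X$X }
  kernel <- match.arg(kernel)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  p <- ncol(X)
  if (p < 1L) stop("need at least one feature")
  Xs <- standardize_columns(X)
  yf <- factor(y)
  remaining <- seq_len(p)
  elim <- integer(0L)
  while (length(remaining) > 1L) {
    Xc <- Xs[, remaining, drop = FALSE]
    g <- if (is.null(gamma)) 1 / ncol(Xc) else gamma
    fit <- e1071::svm(Xc, yf, scale = FALSE, cost = C,
                      kernel = if (kernel == "rbf") "radial" else "linear",
                      gamma = g)
    if (kernel == "linear") {
      w <- crossprod(fit$coefs, fit$SV)
      score <- as.numeric(w)^2
    } else {
      score <- rfe_scores_cpp(fit$SV, as.numeric(fit$coefs), g)
    }
    drop_pos <- order(score, seq_along(score))[1L]
    elim <- c(elim, remaining[drop_pos])
    remaining <- remaining[-drop_pos]
  }
  elim <- c(elim, remaining)
  rev(elim)
}

#' Consensus SVM-RFE ranking over subsampled runs
#'
#' Repeats [svm_rfe_single()] on class-stratified random subsamples of the
#' rows (by default 1000 runs on 90% of the samples) and aggregates the
#' run rankings by positional vote counting: the consensus rank-1 feature
#' is the one appearing most often in rank-1 position across runs; the
#' consensus rank-2 feature is the most frequent among ranks 1-2 excluding
#' the already-chosen feature, and so on. Vote-count ties are broken
#' toward the lower column index. Deterministic given `seed`.
#'
#' @param X numeric matrix or a [feature_table].
#' @param y class labels (ignored for a feature table).
#' @param n_runs number of subsampled RFE runs (default 1000).
#' @param subsample fraction of rows drawn per run, without replacement,
#'   stratified by class (default 0.9).
#' @param seed integer seed controlling the subsampling.
#' @param ... passed to [svm_rfe_single()] (`C`, `kernel`, `gamma`).
#' @return An object of class `ranked_edge_set`: data.frame with columns
#'   `rank`, `column`, `votes` and, when `X` is a feature table, `band`,
#'   `channel_a`, `channel_b`, `mean_A`, `mean_B` (per-condition feature
#'   means, conditions in sorted order).
#' @export
consensus_rank <- function(X, y = NULL, n_runs = 1000L, subsample = 0.9,
                           seed = 1L, ...) {
  feats <- NULL; conditions <- NULL
  if (inherits(X, "feature_table")) {
    feats <- X$features; conditions <- X$conditions; y <- X$y; X <- X$X
  }
  p <- ncol(X)
  cls <- sort(unique(y))
  idx_by_class <- lapply(cls, function(cc) which(y == cc))
  take <- vapply(idx_by_class, function(ii)
    max(1L, as.integer(round(subsample * length(ii)))), integer(1L))
  if (any(take < 2L)) stop("subsample leaves fewer than 2 rows per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rank_mat <- matrix(0L, n_runs, p)
  for (r in seq_len(n_runs)) {
    rows <- unlist(Map(function(ii, k) sample(ii, k), idx_by_class,
                       as.list(take)), use.names = FALSE)
    rank_mat[r, ] <- svm_rfe_single(X[rows, , drop = FALSE], y[rows], ...)
  }
  out <- consensus_from_rankings(rank_mat)
  if (!is.null(feats)) {
    out <- cbind(out, feats[out$column, c("band", "channel_a",
                                          "channel_b")])
    conds <- sort(unique(conditions))
    out$mean_A <- colMeans(X[conditions == conds[1L], out$column,
                             drop = FALSE])
    out$mean_B <- colMeans(X[conditions == conds[2L], out$column,
                             drop = FALSE])
    attr(out, "condition_levels") <- conds
  }
  rownames(out) <- NULL
  structure(out, n_runs = n_runs, subsample = subsample, seed = seed,
            class = c("ranked_edge_set", "data.frame"))
}

#' Aggregate run rankings by positional vote counting
#'
#' The consensus rank-1 feature is the most frequent feature in the
#' rank-1 position across runs; the consensus rank-r feature is the most
#' frequent among positions 1..r, excluding features already chosen.
#' Vote-count ties break toward the lower feature index.
#'
#' @param rank_mat integer matrix, one row per run; `rank_mat[r, pos]` is
#'   the feature placed at rank `pos` by run `r` (each row a permutation
#'   of `1..p`).
#' @return data.frame with columns `rank`, `column` (feature index) and
#'   `votes` (the winning count at selection time).
#' @export
consensus_from_rankings <- function(rank_mat) {
  p <- ncol(rank_mat)
  chosen <- integer(0L)
  votes <- integer(0L)
  tally <- integer(p)
  for (pos in seq_len(p)) {
    tally <- tally + tabulate(rank_mat[, pos], nbins = p)
    open <- setdiff(seq_len(p), chosen)
    win <- open[order(-tally[open], open)][1L]
    chosen <- c(chosen, win)
    votes <- c(votes, tally[win])
  }
  data.frame(rank = seq_len(p), column = chosen, votes = votes)
}

#' Top-k consensus edges with region categories
#'
#' The first `k` rows of a consensus ranking, annotated with the scalp
#' region category of each edge and the direction of the condition
#' difference (which condition has the larger mean PLI).
#'
#' @param ranked a `ranked_edge_set` from [consensus_rank()] built from a
#'   [feature_table].
#' @param k number of edges to keep (default 20).
#' @param mont the [montage] used for region lookup.
#' @return The `ranked_edge_set` restricted to `k` rows, with added
#'   columns `region_category` and `direction`.
#' @export
top_k <- function(ranked, k = 20L, mont = default_montage()) {
  if (k > nrow(ranked))
    stop("requested k = ", k, " but only ", nrow(ranked),
         " ranked edges are available")
  out <- ranked[seq_len(k), , drop = FALSE]
  if (k > 0L && all(c("channel_a", "channel_b") %in% names(out))) {
    out$region_category <- vapply(seq_len(k), function(r)
      edge_region_category(mont, out$channel_a[r], out$channel_b[r]),
      character(1L))
    lv <- attr(ranked, "condition_levels")
    if (is.null(lv)) lv <- c("A", "B")
    out$direction <- ifelse(out$mean_B > out$mean_A,
                            paste(lv[2L], ">", lv[1L]),
                            paste(lv[1L], ">", lv[2L]))
  }
  attributes(out)[c("n_runs", "subsample", "seed", "condition_levels")] <-
    attributes(ranked)[c("n_runs", "subsample", "seed", "condition_levels")]
  class(out) <- c("ranked_edge_set", "data.frame")
  out
}
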