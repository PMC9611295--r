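#' Stratified k-fold cross-validated classification
#'
#' Condition classification from PLI feature vectors with one of three
#' models: RBF-kernel SVM, random forest, or k-nearest neighbours.
#' Folds are stratified by class and fixed by `seed`; feature
#' standardisation is fitted on the training folds only, so no test
#' information leaks into scaling.
#'
#' @param X numeric feature matrix (rows = samples) or a [feature_table].
#' @param y class labels (any two levels; ignored for a feature table).
#' @param model `"svm"` (RBF, default), `"rf"` or `"knn"`.
#' @param folds number of folds (default 10); every class must have at
#'   least `folds` samples.
#' @param seed integer seed fixing the fold assignment (and the forest).
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses
#'   `1/n_features`).
#' @param ntree random-forest size (default 500).
#' @param knn_k neighbourhood size for KNN (default 5).
#' @return An object of class `classification_report`: list with `model`,
#'   `fold_accuracy` (length `folds`), `mean_accuracy`, `sd_accuracy`,
#'   `folds`, `seed`, `n`.
#' @export
crossval_classify <- function(X, y = NULL, model = c("svm", "rf", "knn"),
                              folds = 10L, seed = 1L, cost = 1,
                              gamma = NULL, ntree = 500L, knn_k = 5L) {
  if (inherits(X, "feature_table")) { y <- X$conditions; X <- X$X }
  model <- match.arg(model)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (min(table(y)) < folds)
    stop("every class needs at least ", folds, " samples for ", folds,
         "-fold stratified CV")
  fold_of <- stratified_folds(y, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu, "-"), 2L, sd, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu, "-"), 2L, sd, "/")
    pred <- switch(model,
      svm = {
        g <- if (is.null(gamma)) 1 / ncol(Xtr) else gamma
        fit <- e1071::svm(Xtr, y[tr], scale = FALSE, kernel = "radial",
                          cost = cost, gamma = g)
        stats::predict(fit, Xte)
      },
      rf = {
        fit <- randomForest::randomForest(Xtr, y[tr], ntree = ntree)
        stats::predict(fit, Xte)
      },
      knn = class::knn(Xtr, Xte, y[tr], k = min(knn_k, nrow(Xtr))))
    acc[f] <- mean(pred == y[!tr])
  }
  structure(list(model = model, fold_accuracy = acc,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 folds = folds, seed = seed, n = length(y)),
            class = "classification_report")
}

#' Seed-fixed stratified fold assignment
#'
#' Assigns each sample to one of `folds` cross-validation folds such that
#' every class is spread as evenly as possible across folds. The
#' assignment depends only on the class labels and the seed (not on the
#' order of samples within a class beyond the seeded shuffle), so every
#' sample lands in exactly one test fold.
#'
#' @param y class labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..folds`, parallel to `y`.
#' @export
stratified_folds <- function(y, folds, seed = 1L) {
  y <- factor(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$model, ", ", x$folds,
      "-fold CV on n = ", x$n, "\n  mean accuracy ",
      sprintf("%.3f", x$mean_accuracy), " (sd ",
      sprintf("%.3f", x$sd_accuracy), ")\n", sep = "")
  invisible(x)
}

#' Full four-band PLI feature matrix of a cohort
#'
#' Concatenates the window-averaged PLI of every channel pair across all
#' bands into one feature vector per recording (with 60 channels and four
#' bands: 7080 features), the default representation for condition
#' classification.
#'
#' @param subject_conn named list (by recording id) of per-band lists of
#'   window-averaged connectivity matrices.
#' @param mont the [montage].
#' @return Numeric matrix, rows = recordings, columns named
#'   `band:chA-chB`.
#' @export
full_pli_features <- function(subject_conn, mont = default_montage()) {
  bands <- names(subject_conn[[1L]])
  pairs <- edge_pairs(mont)
  X <- t(vapply(subject_conn, function(sc)
    unlist(lapply(bands, function(b) sc[[b]][pairs]), use.names = FALSE),
    numeric(length(bands) * nrow(pairs))))
  colnames(X) <- unlist(lapply(bands, function(b)
    paste0(b, ":", mont$label[pairs[, 1L]], "-",
           mont$label[pairs[, 2L]])))
  rownames(X) <- names(subject_conn)
  X
}
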