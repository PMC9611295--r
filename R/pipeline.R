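#' Pipeline configuration
#'
#' Bundles and validates the parameters of every stage before any stage
#' runs: the input cohort (a [synthetic_config] or a directory of matrix
#' files with a manifest), band list, window specification, sparsity grid,
#' edge-selection alpha, consensus-RFE settings and classification
#' settings.
#'
#' @param input a [synthetic_config], or the path of a directory holding a
#'   `manifest.csv` (columns `id`, `subject`, `condition`, `path`) and one
#'   matrix file per recording.
#' @param bands named list of [band_spec]s.
#' @param window a [window_spec].
#' @param sparsity_grid ascending sparsity grid.
#' @param alpha edge-selection significance threshold.
#' @param rfe list of consensus-RFE settings: `n_runs`, `subsample`, `C`,
#'   `kernel`.
#' @param classify list of classification settings: `models`, `folds`.
#' @param n_top number of consensus edges to report.
#' @param seed master seed for the RFE subsampling and CV folds.
#' @param mont the [montage].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = synthetic_config(),
                            bands = eeg_bands(),
                            window = window_spec(),
                            sparsity_grid = default_sparsity_grid(),
                            alpha = 0.05,
                            rfe = list(n_runs = 1000L, subsample = 0.9,
                                       C = 1, kernel = "rbf"),
                            classify = list(models = c("svm", "rf", "knn"),
                                            folds = 10L),
                            n_top = 20L, seed = 1L,
                            mont = default_montage()) {
  stopifnot(inherits(window, "window_spec"))
  if (is.unsorted(sparsity_grid, strictly = TRUE))
    stop("sparsity_grid must be ascending")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!(is.character(input) || inherits(input, "synthetic_config")))
    stop("input must be a synthetic_config or a cohort directory path")
  structure(list(input = input, bands = bands, window = window,
                 sparsity_grid = sparsity_grid, alpha = alpha, rfe = rfe,
                 classify = classify, n_top = as.integer(n_top),
                 seed = as.integer(seed), mont = mont),
            class = "pipeline_config")
}

read_cohort <- function(dir, fs, mont) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  recs <- lapply(man$path, read_recording_matrix, fs = fs,
                 labels = mont$label)
  names(recs) <- man$id
  structure(list(recordings = recs, manifest = man), class = "cohort")
}

#' Window-averaged connectivity of every recording in a cohort
#'
#' Applies the common average reference, band-decomposes each recording
#' and returns the window-averaged PLI matrix per band per recording.
#'
#' @param coh a `cohort`.
#' @param bands named list of [band_spec]s.
#' @param window a [window_spec].
#' @return Named list (by recording id): each element a named list of
#'   per-band channels x channels mean-PLI matrices.
#' @export
cohort_mean_connectivity <- function(coh, bands = eeg_bands(),
                                     window = window_spec()) {
  lapply(coh$recordings, function(rec) {
    rec <- average_reference(rec)
    mean_connectivity(connectivity_tensor(rec, bands, window))
  })
}

#' Run the full analysis pipeline
#'
#' simulate/load -> preprocess -> sliding-window PLI -> sparsity-swept
#' graph metrics with AUC -> ANOVA comparisons and edge selection ->
#' consensus SVM-RFE ranking -> cross-validated classification. All stage
#' outputs are written to `out_dir` as plain CSV/JSON; reruns with an
#' identical config produce identical files.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param fs sampling rate of matrix-file cohorts (ignored for synthetic
#'   input).
#' @return Invisibly, a list with elements `auc_table`,
#'   `feature_comparisons`, `edge_sets`, `ranked` (or `NULL`), `top`
#'   (or `NULL`), `reports`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, fs = 200) {
  stopifnot(inherits(config, "pipeline_config"))
  mont <- config$mont
  coh <- if (inherits(config$input, "synthetic_config"))
    generate_cohort(config$input, mont)
  else read_cohort(config$input, fs, mont)
  message("pipeline: ", length(coh$recordings), " recordings")

  subject_conn <- cohort_mean_connectivity(coh, config$bands,
                                           config$window)
  message("pipeline: connectivity done")

  profiles <- lapply(subject_conn, function(sc)
    lapply(sc, sparsity_sweep, grid = config$sparsity_grid))
  auc_table <- do.call(rbind, lapply(names(profiles), function(id) {
    k <- match(id, coh$manifest$id)
    do.call(rbind, lapply(names(profiles[[id]]), function(b) {
      auc <- profiles[[id]][[b]]$auc
      data.frame(id = id, subject = coh$manifest$subject[k],
                 condition = coh$manifest$condition[k], band = b,
                 metric = names(auc), auc = unname(auc))
    }))
  }))
  rownames(auc_table) <- NULL
  message("pipeline: network metrics done")

  feature_comparisons <- compare_network_features(auc_table)
  conditions <- coh$manifest$condition[match(names(subject_conn),
                                             coh$manifest$id)]
  edge_sets <- select_significant_edges(subject_conn, conditions,
                                        alpha = config$alpha, mont = mont)
  n_sig <- sum(vapply(edge_sets, nrow, integer(1L)))
  message("pipeline: stats done (", n_sig, " significant edges)")

  ranked <- NULL; top <- NULL
  if (n_sig > 0L) {
    ft <- feature_table(subject_conn, conditions, edge_sets, mont)
    ranked <- consensus_rank(ft, n_runs = config$rfe$n_runs,
                             subsample = config$rfe$subsample,
                             seed = config$seed, C = config$rfe$C,
                             kernel = config$rfe$kernel)
    top <- top_k(ranked, min(config$n_top, nrow(ranked)), mont)
    message("pipeline: ranking done")
  } else {
    message("pipeline: ranking skipped (no significant edges at alpha = ",
            config$alpha, ")")
  }

  Xfull <- full_pli_features(subject_conn, mont)
  reports <- lapply(config$classify$models, function(m)
    crossval_classify(Xfull, conditions, model = m,
                      folds = config$classify$folds, seed = config$seed))
  names(reports) <- config$classify$models
  message("pipeline: classification done")

  result <- list(auc_table = auc_table,
                 feature_comparisons = feature_comparisons,
                 edge_sets = edge_sets, ranked = ranked, top = top,
                 reports = reports, manifest = coh$manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(result$auc_table, "network_auc.csv")
  wcsv(result$feature_comparisons, "feature_comparisons.csv")
  edges <- do.call(rbind, lapply(names(result$edge_sets), function(b) {
    es <- result$edge_sets[[b]]
    if (!nrow(es)) return(NULL)
    cbind(band = b, as.data.frame(es))
  }))
  if (!is.null(edges)) wcsv(edges, "significant_edges.csv")
  if (!is.null(result$ranked)) wcsv(as.data.frame(result$ranked),
                                    "ranked_edges.csv")
  if (!is.null(result$top)) {
    wcsv(as.data.frame(result$top), "top_edges.csv")
    writeLines(paste(result$top$channel_a, result$top$channel_b,
                     round(pmax(result$top$mean_A, result$top$mean_B), 4)),
               file.path(out_dir, "top_edges.txt"))
  }
  cls <- do.call(rbind, lapply(result$reports, function(r)
    data.frame(model = r$model, fold = seq_along(r$fold_accuracy),
               accuracy = r$fold_accuracy)))
  wcsv(cls, "classification.csv")
  summary <- list(
    seed = config$seed, alpha = config$alpha,
    sparsity_grid = config$sparsity_grid,
    n_recordings = nrow(result$manifest),
    n_significant_edges = vapply(result$edge_sets, nrow, integer(1L)),
    mean_accuracy = vapply(result$reports, function(r) r$mean_accuracy,
                           numeric(1L)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
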