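#' Classical one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance across `k >= 2` groups: the
#' F statistic on `(k - 1, N - k)` degrees of freedom and its upper-tail
#' p value. When the data carry no variance at all the comparison is
#' undefined; the result is then `F = 0`, `p = 1` with attribute
#' `degenerate = TRUE`.
#'
#' @param groups list of numeric vectors, one per group, each with at
#'   least 2 values.
#' @return List with elements `F`, `p`, `df` (length 2), `means`, `sds`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$F  # 13.5
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), sizes))
  means <- vapply(groups, mean, numeric(1L))
  sds <- vapply(groups, stats::sd, numeric(1L))
  if (stats::var(vals) == 0)
    return(structure(list(F = 0, p = 1,
                          df = c(length(groups) - 1L,
                                 length(vals) - length(groups)),
                          means = means, sds = sds), degenerate = TRUE))
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter), means = means, sds = sds)
}

#' Compare AUC network features between conditions
#'
#' One-way ANOVA per (band, metric) cell on the per-subject AUC values of
#' the four weighted graph metrics.
#'
#' @param auc_table data.frame with columns `subject`, `condition`, `band`,
#'   `metric`, `auc` (one row per subject x condition x band x metric), as
#'   produced by the pipeline.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per band x metric: `band`, `metric`,
#'   `F`, `p`, per-condition means and SDs, and `significant` at the 0.05
#'   level.
#' @export
compare_network_features <- function(auc_table, alpha = 0.05) {
  need <- c("subject", "condition", "band", "metric", "auc")
  if (!all(need %in% names(auc_table)))
    stop("auc_table must have columns ", paste(need, collapse = ", "))
  conds <- sort(unique(auc_table$condition))
  if (length(conds) < 2L) stop("need at least 2 conditions")
  subj_sets <- lapply(conds, function(cc)
    sort(unique(auc_table$subject[auc_table$condition == cc])))
  if (!all(vapply(subj_sets[-1L], identical, logical(1L), subj_sets[[1L]])))
    stop("conditions must cover the same subject set")
  cells <- unique(auc_table[, c("band", "metric")])
  out <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- auc_table[auc_table$band == cells$band[r] &
                       auc_table$metric == cells$metric[r], ]
    groups <- lapply(conds, function(cc) sub$auc[sub$condition == cc])
    a <- anova_oneway(groups)
    stats_row <- data.frame(band = cells$band[r], metric = cells$metric[r],
                            F = a$F, p = a$p)
    for (k in seq_along(conds)) {
      stats_row[[paste0("mean_", conds[k])]] <- a$means[k]
      stats_row[[paste0("sd_", conds[k])]] <- a$sds[k]
    }
    stats_row$significant <- a$p < alpha
    stats_row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select edges whose PLI differs between conditions
#'
#' Per band, runs a one-way ANOVA across conditions on every channel
#' pair's window-averaged PLI (one value per subject per condition) and
#' retains edges with `p < alpha`. No multiple-testing correction is
#' applied by default, matching the selection-before-ranking design; set
#' `fdr = TRUE` to apply Benjamini-Hochberg instead.
#'
#' @param subject_conn named list (by recording id) of per-band lists of
#'   window-averaged connectivity matrices, i.e.
#'   `subject_conn[[id]][[band]]` is a channels x channels matrix.
#' @param conditions character vector of condition labels, parallel to
#'   `subject_conn`.
#' @param alpha significance threshold (default 0.05).
#' @param mont the [montage] naming the channels.
#' @param fdr apply Benjamini-Hochberg correction before thresholding.
#' @return Named list per band of class-`significant_edge_set`
#'   data.frames: `edge` (canonical index), `i`, `j`, `channel_a`,
#'   `channel_b`, `F`, `p`, sorted by p.
#' @export
select_significant_edges <- function(subject_conn, conditions,
                                     alpha = 0.05,
                                     mont = default_montage(),
                                     fdr = FALSE) {
  if (length(subject_conn) != length(conditions))
    stop("subject_conn and conditions must be parallel")
  bands <- names(subject_conn[[1L]])
  conds <- sort(unique(conditions))
  n <- nrow(mont)
  pairs <- edge_pairs(n)
  out <- lapply(bands, function(b) {
    # edges x recordings matrix of mean PLI values
    em <- vapply(subject_conn, function(sc) sc[[b]][pairs],
                 numeric(nrow(pairs)))
    fp <- t(apply(em, 1L, function(v) {
      a <- anova_oneway(split(v, conditions))
      c(a$F, a$p)
    }))
    p <- if (fdr) stats::p.adjust(fp[, 2L], "BH") else fp[, 2L]
    keep <- which(p < alpha)
    res <- data.frame(edge = keep, i = pairs[keep, 1L], j = pairs[keep, 2L],
                      channel_a = mont$label[pairs[keep, 1L]],
                      channel_b = mont$label[pairs[keep, 2L]],
                      F = fp[keep, 1L], p = p[keep])
    res <- res[order(res$p, res$edge), ]
    rownames(res) <- NULL
    structure(res, alpha = alpha, class = c("significant_edge_set",
                                            "data.frame"))
  })
  names(out) <- bands
  out
}
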