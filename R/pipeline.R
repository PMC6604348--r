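#' Run the full annotation pipeline
#'
#' End-to-end analysis of a genes x cells expression matrix:
#' preprocessing (expression filter, per-cell normalization, log2 transform,
#' variation filter), projection on the top principal components, selection
#' of the number of clusters from the mini-batch K-means stability curve
#' (unless `n_clusters` is given), Ward agglomerative clustering, marker
#' approval voting against the random-cluster null, and an optional t-SNE
#' layout for figures.
#'
#' @param expr genes x cells matrix (see [expression_matrix()]).
#' @param db a [marker_db()].
#' @param theta variation-filter threshold (default 0.3).
#' @param zeta marker-support z-score threshold (default 0.3).
#' @param n_clusters fixed number of clusters, or `NULL` (default) to select
#'   it from the stability curve.
#' @param n_grid candidate cluster numbers for the stability curve
#'   (default 4:16).
#' @param ari_reps partitions per stability run (default 12).
#' @param ari_runs independent stability runs (default 200).
#' @param pcs number of principal components (default 100).
#' @param n_random null-model randomizations (default 10000).
#' @param seed master seed; stage seeds are derived from it so the whole run
#'   is reproducible.
#' @param perplexity t-SNE perplexity (default 30).
#' @param tsne compute the 2-D layout (default TRUE; skip for speed).
#' @param unknown_rule see [assign_types()].
#' @param keep_null_samples keep the null score array for histogram figures.
#' @return object of class `pollsort_fit`: `processed`, `reduced`,
#'   `ari` (`NULL` when `n_clusters` was fixed), `assignment`, `markers`
#'   (the `marker_matrix`), `vote`, `tsne` (or `NULL`), `cell_types`
#'   (label per cell), `params`.
#' @export
run_pipeline <- function(expr, db, theta = 0.3, zeta = 0.3,
                         n_clusters = NULL, n_grid = 4:16,
                         ari_reps = 12L, ari_runs = 200L, pcs = 100L,
                         n_random = 10000L, seed = 0L, perplexity = 30,
                         tsne = TRUE, unknown_rule = "lambda_nonpos",
                         keep_null_samples = FALSE) {
  check_expression(expr)
  stopifnot(inherits(db, "marker_db"))
  seed <- as.integer(seed)
  ps_log("run_pipeline: ", nrow(expr), " genes x ", ncol(expr), " cells; ",
         "theta=", theta, " zeta=", zeta, " pcs=", pcs,
         " n_random=", n_random, " seed=", seed)

  proc <- preprocess(expr, theta)
  reduced <- pca_reduce(proc$log_matrix[proc$variable_gene_mask, , drop = FALSE],
                        k = pcs)
  ps_log("pca_reduce: ", reduced$k_pc, " components, ",
         round(100 * reduced$explained_variance_fraction, 1),
         "% variance explained")

  curve <- NULL
  if (is.null(n_clusters)) {
    curve <- ari_curve(reduced, n_values = n_grid, reps_per_run = ari_reps,
                       n_runs = ari_runs, seed = seed + 1L)
    n_clusters <- select_n(curve)
    ps_log("select_n: n = ", n_clusters)
  }
  assignment <- cluster_cells(reduced, n_clusters)

  mm <- marker_matrix(db, rownames(proc$log_matrix))
  vote <- vote_clusters(proc$log_matrix, assignment, mm, zeta = zeta,
                        n_random = n_random, seed = seed + 2L,
                        unknown_rule = unknown_rule,
                        keep_null_samples = keep_null_samples)

  coords <- if (tsne) tsne_layout(reduced, seed = seed + 3L,
                                  perplexity = perplexity) else NULL

  structure(list(processed = proc, reduced = reduced, ari = curve,
                 assignment = assignment, markers = mm, vote = vote,
                 tsne = coords,
                 cell_types = stats::setNames(
                   vote$table$cell_type[assignment$labels],
                   names(assignment$labels)),
                 params = list(theta = theta, zeta = zeta,
                               n_clusters = assignment$n, n_grid = n_grid,
                               ari_reps = ari_reps, ari_runs = ari_runs,
                               pcs = pcs, n_random = n_random, seed = seed,
                               perplexity = perplexity,
                               unknown_rule = unknown_rule)),
            class = "pollsort_fit")
}

#' @export
print.pollsort_fit <- function(x, ...) {
  cat("pollsort_fit:", length(x$assignment$labels), "cells,",
      x$assignment$n, "clusters\n")
  print(x$vote$table[, c("cluster", "cell_type", "max_lambda",
                         "support_count", "low_support")], row.names = FALSE)
  invisible(x)
}
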