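#' Principal-component reduction
#'
#' Projects cells onto the top principal components of the gene-centered
#' log-expression matrix (genes are centered, not scaled). Clustering and the
#' t-SNE layout both operate on this reduced representation.
#'
#' @param log_matrix genes x cells matrix (normally restricted to the
#'   high-variation genes).
#' @param k number of components requested (default 100); if fewer exist,
#'   all available components are returned with a warning.
#' @return object of class `reduced_matrix`: `components` (k_pc x cells
#'   score matrix), `explained_variance_fraction`, `k_pc`.
#' @export
pca_reduce <- function(log_matrix, k = 100) {
  p <- ncol(log_matrix)
  if (p < 2) stop("PCA needs at least 2 cells")
  k_max <- min(p - 1L, nrow(log_matrix))
  k_pc <- min(k, k_max)
  if (k_pc < k)
    warning("only ", k_pc, " principal components available (requested ", k, ")")
  pc <- stats::prcomp(t(log_matrix), center = TRUE, scale. = FALSE, rank. = k_pc)
  scores <- t(pc$x)                      # k_pc x cells
  totvar <- sum(pc$sdev^2)
  evf <- if (totvar > 0) sum(pc$sdev[seq_len(k_pc)]^2) / totvar else 0
  structure(list(components = scores,
                 explained_variance_fraction = evf,
                 k_pc = k_pc),
            class = "reduced_matrix")
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells under
#' the permutation model: 1 for identical partitions, about 0 for independent
#' ones. When both partitions are trivial (the denominator vanishes) the
#' partitions are identical and 1 is returned.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions have different lengths: ", length(a), " vs ", length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(n_pairs2(tab))
  sum_a <- sum(n_pairs2(rowSums(tab)))
  sum_b <- sum(n_pairs2(colSums(tab)))
  expected <- sum_a * sum_b / n_pairs2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Mini-batch K-means partition
#'
#' Stochastic K-means with per-center learning-rate updates on random
#' mini-batches; the stochastic clusterer behind the stability (ARI) curve.
#' Centers are seeded with k-means++ sampling; each call draws a fresh
#' random initialization from the current RNG state.
#'
#' @param x cells x dims matrix.
#' @param k number of centers.
#' @param batch_size mini-batch size (default `min(100, cells)`).
#' @param n_iter number of batch updates (default 100).
#' @return integer label per cell in `1..k` (some labels may be unused when a
#'   center attracts no cells).
#' @export
minibatch_kmeans <- function(x, k, batch_size = min(100L, nrow(x)),
                             n_iter = 100L) {
  n <- nrow(x)
  if (k > n) stop("more centers than cells")
  # k-means++ seeding: spread initial centers out, avoiding the local optima
  # plain random init falls into when two seeds land in one tight cluster
  centers <- x[sample.int(n, 1), , drop = FALSE]
  if (k > 1) {
    d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
    for (j in 2:k) {
      pick <- if (all(d2 == 0)) sample.int(n, 1) else
        sample.int(n, 1, prob = d2)
      centers <- rbind(centers, x[pick, , drop = FALSE])
      d2 <- pmin(d2, rowSums((x - rep(x[pick, ], each = n))^2))
    }
  }
  counts <- rep(0, k)
  nearest <- function(pts) {
    # argmin ||p - c||^2 = argmax p.c - |c|^2/2
    score <- pts %*% t(centers) -
      rep(rowSums(centers^2) / 2, each = nrow(pts))
    max.col(score, ties.method = "first")
  }
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, min(batch_size, n))
    b <- x[idx, , drop = FALSE]
    a <- nearest(b)
    for (j in unique(a)) {
      pts <- b[a == j, , drop = FALSE]
      counts[j] <- counts[j] + nrow(pts)
      lr <- nrow(pts) / counts[j]
      centers[j, ] <- (1 - lr) * centers[j, ] + lr * colMeans(pts)
    }
  }
  nearest(x)
}

#' Cluster-number stability curve
#'
#' For each candidate number of clusters `n`, the cells are partitioned
#' `reps_per_run` times with [minibatch_kmeans()] and the adjusted Rand index
#' is averaged over all unordered pairs of partitions (66 pairs when
#' `reps_per_run = 12`); this is repeated over `n_runs` independent runs to
#' obtain a mean and an error bar per `n`.
#'
#' @param reduced a `reduced_matrix` from [pca_reduce()].
#' @param n_values integer grid of candidate cluster numbers (default 4:16).
#' @param reps_per_run partitions per run (default 12; must be >= 2).
#' @param n_runs independent runs (default 200).
#' @param seed RNG seed making the curve reproducible.
#' @param batch_size,n_iter mini-batch K-means controls.
#' @return object of class `ari_curve`: data frame `curve` with columns
#'   `n`, `mean_ari`, `sd_ari`; plus `reps_per_run`, `n_runs`, `n_pairs`.
#' @export
ari_curve <- function(reduced, n_values = 4:16, reps_per_run = 12L,
                      n_runs = 200L, seed = 0L,
                      batch_size = NULL, n_iter = 100L) {
  stopifnot(inherits(reduced, "reduced_matrix"))
  x <- t(reduced$components)             # cells x dims
  n_cells <- nrow(x)
  if (reps_per_run < 2) stop("reps_per_run must be >= 2")
  if (any(n_values > n_cells)) stop("grid contains n larger than the cell count")
  if (is.null(batch_size)) batch_size <- min(100L, n_cells)
  pair_idx <- utils::combn(reps_per_run, 2)
  n_pairs <- ncol(pair_idx)
  withr::with_seed(seed, {
    res <- lapply(n_values, function(nv) {
      run_means <- vapply(seq_len(n_runs), function(run) {
        parts <- lapply(seq_len(reps_per_run), function(r)
          minibatch_kmeans(x, nv, batch_size, n_iter))
        mean(vapply(seq_len(n_pairs), function(q)
          adjusted_rand_index(parts[[pair_idx[1, q]]],
                              parts[[pair_idx[2, q]]]),
          numeric(1)))
      }, numeric(1))
      c(mean(run_means), stats::sd(run_means))
    })
  })
  res <- do.call(rbind, res)
  structure(list(curve = data.frame(n = as.integer(n_values),
                                    mean_ari = res[, 1],
                                    sd_ari = ifelse(is.na(res[, 2]), 0, res[, 2])),
                 reps_per_run = as.integer(reps_per_run),
                 n_runs = as.integer(n_runs),
                 n_pairs = n_pairs),
            class = "ari_curve")
}

#' Select the number of clusters from a stability curve
#'
#' Scans the curve from the largest `n` downward and returns the first
#' interior peak: the first `n` with `mean_ari(n) > mean_ari(n+1)` and
#' `mean_ari(n) >= mean_ari(n-1)`. The stability maximum at small `n` is
#' uninformative (few big clusters always agree), so if no interior peak
#' exists the argmax over the grid excluding its smallest point is returned.
#' A flat curve returns the largest `n` with a warning.
#'
#' @param curve an `ari_curve` (or a data frame with columns `n`, `mean_ari`).
#' @return the selected integer `n`.
#' @export
select_n <- function(curve) {
  cv <- if (inherits(curve, "ari_curve")) curve$curve else curve
  cv <- cv[order(cv$n), ]
  g <- nrow(cv)
  if (g < 3) stop("need at least 3 grid points to locate a peak")
  m <- cv$mean_ari
  if (all(m == m[1])) {
    warning("degenerate (flat) stability curve; returning the largest n")
    return(cv$n[g])
  }
  for (i in seq(g - 1, 2)) {
    if (m[i] > m[i + 1] && m[i] >= m[i - 1]) return(cv$n[i])
  }
  cv$n[-1][which.max(m[-1])]
}

#' Agglomerative clustering of cells in PC space
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between cell
#' scores, cut into exactly `n` clusters. Deterministic for fixed input.
#'
#' @param reduced a `reduced_matrix`.
#' @param n number of clusters, `2 <= n <= cells`.
#' @return object of class `cluster_assignment`: integer `labels` per cell
#'   (named by barcode, values `1..n`), `n`, `sizes`.
#' @export
cluster_cells <- function(reduced, n) {
  stopifnot(inherits(reduced, "reduced_matrix"))
  n_cells <- ncol(reduced$components)
  if (n < 2 || n > n_cells) stop("n must be in [2, ", n_cells, "]")
  hc <- stats::hclust(stats::dist(t(reduced$components)), method = "ward.D2")
  labels <- stats::cutree(hc, k = n)
  structure(list(labels = labels, n = as.integer(n),
                 sizes = as.integer(tabulate(labels, n))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$labels), "cells in", x$n,
      "clusters; sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Two-dimensional t-SNE layout
#'
#' Embeds cells in two dimensions from the full PC-space representation
#' (not merely the top two components); used for figures only.
#'
#' @param reduced a `reduced_matrix`.
#' @param seed RNG seed (layout is deterministic given the seed).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically with
#'   a warning when the cell count is too small for it).
#' @return cells x 2 coordinate matrix (rownames = barcodes).
#' @export
tsne_layout <- function(reduced, seed = 0L, perplexity = 30) {
  stopifnot(inherits(reduced, "reduced_matrix"))
  x <- t(reduced$components)
  n <- nrow(x)
  if (n < 5) stop("too few cells (", n, ") for a t-SNE layout")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning("perplexity reduced from ", perplexity, " to ", max_perp,
            " for ", n, " cells")
    perplexity <- max_perp
  }
  emb <- withr::with_seed(seed,
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE))
  coords <- emb$Y
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("tSNE1", "tSNE2")
  coords
}
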