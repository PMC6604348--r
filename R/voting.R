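#' Marker/centroid matrix
#'
#' Mean log-expression of each marker across the cells of each cluster.
#'
#' @param marker_expression markers x cells matrix (log units), i.e. the
#'   preprocessed log-matrix restricted to marker genes.
#' @param assignment a `cluster_assignment`.
#' @return matrix `Y` (markers x clusters).
#' @export
centroid_matrix <- function(marker_expression, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (nrow(marker_expression) == 0) stop("no marker genes present")
  if (ncol(marker_expression) != length(assignment$labels))
    stop("cell count mismatch between expression and assignment")
  sums <- t(rowsum(t(marker_expression),
                   group = factor(assignment$labels,
                                  levels = seq_len(assignment$n))))
  Y <- sweep(sums, 2, assignment$sizes, "/")
  colnames(Y) <- seq_len(assignment$n)
  Y
}

#' Centroid z-scores and marker support calls
#'
#' For each marker, standardizes its cluster centroids across clusters
#' (population standard deviation; every centroid weighted equally) and calls
#' a marker "supported" in a cluster when its z-score reaches the threshold
#' `zeta`. Markers with identical centroids in all clusters carry no
#' discriminative signal and get z-score 0 everywhere (no support).
#'
#' @param Y markers x clusters centroid matrix.
#' @param zeta support threshold (default 0.3). Raising `zeta` can only
#'   shrink the supported set.
#' @return list with `Z` (z-scores) and `Z_support` (binary, `Z >= zeta`).
#' @export
support_matrix <- function(Y, zeta = 0.3) {
  if (ncol(Y) < 2) stop("z-scores undefined with a single cluster")
  mu <- rowMeans(Y)
  sd_ <- row_pop_sd(Y)
  sd_[sd_ == 0] <- Inf
  Z <- (Y - mu) / sd_
  list(Z = Z, Z_support = (Z >= zeta) * 1)
}

#' Approval-vote matrix
#'
#' Each supported marker approves every cell type listing it, with weight
#' `M_tilde[k, m]`; per-cluster scores are normalized so that each column of
#' `V` sums to one. Clusters in which no supported marker is known to any
#' cell type get an all-zero column, reported in the `"degenerate"`
#' attribute.
#'
#' @param M_tilde cell-types x markers weight matrix.
#' @param Z_support binary markers x clusters support matrix.
#' @return matrix `V` (cell types x clusters) with attribute `degenerate`
#'   (logical per cluster).
#' @export
vote_matrix <- function(M_tilde, Z_support) {
  if (ncol(M_tilde) != nrow(Z_support))
    stop("marker axes disagree: ", ncol(M_tilde), " vs ", nrow(Z_support))
  W <- M_tilde %*% Z_support
  denom <- colSums(W)
  degenerate <- denom == 0
  denom[degenerate] <- 1
  V <- sweep(W, 2, denom, "/")
  V[, degenerate] <- 0
  attr(V, "degenerate") <- unname(degenerate)
  V
}

# random size-preserving cluster memberships for one chunk of replicates,
# returned as a sparse cells x (n_clusters * reps) column-mean operator
null_membership <- function(n_cells, sizes, reps) {
  n <- length(sizes)
  i <- as.vector(vapply(seq_len(reps), function(r) sample.int(n_cells),
                        integer(n_cells)))
  j_one <- rep.int(seq_len(n), times = sizes)
  j <- rep(j_one, times = reps) + rep((seq_len(reps) - 1L) * n, each = n_cells)
  x <- rep(rep.int(1 / sizes, times = sizes), times = reps)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_cells, n * reps))
}

#' Null distributions of the approval scores
#'
#' Randomizes the clusters by cutting a uniformly random permutation of all
#' cells into clusters of the observed sizes, recomputes the centroid,
#' support and vote steps on each randomized configuration, and summarizes
#' the resulting score distribution per (cell type, cluster) pair by its mean
#' and (population) standard deviation. The null accounts for cluster sizes,
#' the overall marker expression distribution and marker-count imbalance.
#'
#' @param marker_expression markers x cells matrix (log units).
#' @param cluster_sizes observed cluster sizes; must sum to the cell count.
#' @param M_tilde cell-types x markers weight matrix.
#' @param zeta support threshold, re-applied within every replicate.
#' @param n_random number of randomizations (default 10000).
#' @param seed RNG seed.
#' @param chunk replicates processed per vectorized block (memory knob; has
#'   no effect on results).
#' @param keep_samples set `TRUE` to also return the full array of replicate
#'   scores (types x clusters x n_random), e.g. for histogram figures.
#' @return list with `null_mean`, `null_std` (types x clusters), `n_random`,
#'   and optionally `samples`.
#' @export
null_vote_distributions <- function(marker_expression, cluster_sizes, M_tilde,
                                    zeta = 0.3, n_random = 10000L, seed = 0L,
                                    chunk = 200L, keep_samples = FALSE) {
  n_cells <- ncol(marker_expression)
  if (sum(cluster_sizes) != n_cells)
    stop("cluster sizes sum to ", sum(cluster_sizes), " but there are ",
         n_cells, " cells")
  if (n_random < 2) stop("n_random must be >= 2")
  n_cl <- length(cluster_sizes)
  K <- nrow(M_tilde)
  vsum <- matrix(0, K, n_cl)
  v2sum <- matrix(0, K, n_cl)
  samples <- if (keep_samples) array(NA_real_, c(K, n_cl, n_random)) else NULL
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_random) {
      reps <- min(chunk, n_random - done)
      A <- null_membership(n_cells, cluster_sizes, reps)
      Y <- as.matrix(marker_expression %*% A)      # markers x (n_cl*reps)
      # per-replicate row means / population sds across the n_cl clusters
      blk <- Matrix::sparseMatrix(i = seq_len(n_cl * reps),
                                  j = rep(seq_len(reps), each = n_cl),
                                  x = 1 / n_cl)
      mu <- as.matrix(Y %*% blk)                   # markers x reps
      m2 <- as.matrix(Y^2 %*% blk)
      sd_ <- sqrt(pmax(m2 - mu^2, 0))
      sd_[sd_ == 0] <- Inf
      expand <- rep(seq_len(reps), each = n_cl)
      Zs <- ((Y - mu[, expand]) / sd_[, expand] >= zeta) * 1
      W <- M_tilde %*% Zs                          # K x (n_cl*reps)
      denom <- colSums(W)
      denom[denom == 0] <- 1
      V <- sweep(W, 2, denom, "/")
      # accumulate per-(k, c) first and second moments over replicates
      coll <- Matrix::sparseMatrix(i = seq_len(n_cl * reps),
                                   j = rep(seq_len(n_cl), times = reps),
                                   x = 1, dims = c(n_cl * reps, n_cl))
      vsum <- vsum + as.matrix(V %*% coll)
      v2sum <- v2sum + as.matrix(V^2 %*% coll)
      if (keep_samples)
        samples[, , done + seq_len(reps)] <- array(V, c(K, n_cl, reps))
      done <- done + reps
    }
  })
  null_mean <- vsum / n_random
  null_std <- sqrt(pmax(v2sum / n_random - null_mean^2, 0))
  dimnames(null_mean) <- dimnames(null_std) <-
    list(rownames(M_tilde), seq_len(n_cl))
  out <- list(null_mean = null_mean, null_std = null_std,
              n_random = as.integer(n_random))
  if (keep_samples) out$samples <- samples
  out
}

#' Significance z-scores of the voting results
#'
#' Standardizes the observed approval scores against the random-cluster null.
#' Where the null is degenerate (zero spread) a documented sentinel of
#' magnitude 1e9 is used: 0 when the observed score equals the null mean,
#' otherwise +/- 1e9 with the sign of the deviation.
#'
#' @param V observed types x clusters vote matrix.
#' @param null_mean,null_std null summaries from [null_vote_distributions()].
#' @param large sentinel magnitude for zero-spread nulls (default 1e9).
#' @return matrix `Lambda` (types x clusters).
#' @export
assignment_zscores <- function(V, null_mean, null_std, large = 1e9) {
  stopifnot(all(dim(V) == dim(null_mean)), all(dim(V) == dim(null_std)))
  Lambda <- (V - null_mean) / null_std
  zero <- null_std == 0
  if (any(zero)) {
    dev <- V[zero] - null_mean[zero]
    Lambda[zero] <- sign(dev) * large
    ps_log("assignment_zscores: ", sum(zero),
           " zero-spread null cell(s) replaced by the +/-", large, " sentinel")
  }
  dimnames(Lambda) <- dimnames(V)
  Lambda
}

#' Final cluster-to-cell-type assignment
#'
#' Labels each cluster with the cell type maximizing its significance
#' z-score, counts the supporting markers of the winning type (markers both
#' listed for that type and supported in the cluster), and flags clusters
#' with 3 or fewer supporting markers as low-confidence. A cluster whose best
#' z-score is not positive, or which has no supporting marker, is labeled
#' `"Unknown"` (rule switchable via `unknown_rule`).
#'
#' @param Lambda types x clusters significance matrix.
#' @param M binary types x markers matrix.
#' @param Z_support binary markers x clusters support matrix.
#' @param unknown_rule `"lambda_nonpos"` (default) or `"off"`.
#' @return data frame, one row per cluster: `cluster`, `cell_type`,
#'   `best_type` (argmax type regardless of the Unknown rule), `max_lambda`,
#'   `support_count`, `low_support`.
#' @export
assign_types <- function(Lambda, M, Z_support,
                         unknown_rule = c("lambda_nonpos", "off")) {
  unknown_rule <- match.arg(unknown_rule)
  n_cl <- ncol(Lambda)
  best <- apply(Lambda, 2, which.max)    # ties: lowest type index
  ties <- vapply(seq_len(n_cl), function(c)
    sum(Lambda[, c] == Lambda[best[c], c]) > 1, logical(1))
  if (any(ties))
    ps_log("assign_types: argmax tie in cluster(s) ",
           paste(which(ties), collapse = ", "),
           "; lowest type index wins")
  best_type <- rownames(Lambda)[best]
  max_lambda <- Lambda[cbind(best, seq_len(n_cl))]
  support_count <- vapply(seq_len(n_cl), function(c)
    sum(M[best[c], ] == 1 & Z_support[, c] == 1), numeric(1))
  label <- best_type
  if (unknown_rule == "lambda_nonpos")
    label[max_lambda <= 0 | support_count == 0] <- "Unknown"
  data.frame(cluster = seq_len(n_cl),
             cell_type = label,
             best_type = best_type,
             max_lambda = max_lambda,
             support_count = as.integer(support_count),
             low_support = support_count <= 3,
             stringsAsFactors = FALSE)
}

#' Run the full voting stage on a clustering
#'
#' Convenience wrapper chaining [centroid_matrix()], [support_matrix()],
#' [vote_matrix()], [null_vote_distributions()], [assignment_zscores()] and
#' [assign_types()].
#'
#' @param log_matrix preprocessed genes x cells log-matrix (all expressed
#'   genes; the marker rows are extracted internally).
#' @param assignment a `cluster_assignment`.
#' @param mm a `marker_matrix` (see [marker_matrix()]).
#' @param zeta support threshold (default 0.3).
#' @param n_random null randomizations (default 10000).
#' @param seed RNG seed for the null model.
#' @param unknown_rule see [assign_types()].
#' @param keep_null_samples keep the full null score array (for figures).
#' @return object of class `vote_result` with elements `Y`, `Z`, `Z_support`,
#'   `zeta`, `V`, `degenerate`, `null_mean`, `null_std`, `n_random`,
#'   `Lambda`, `table` (per-cluster assignment), `types`, `markers`, and
#'   optionally `null_samples`.
#' @export
vote_clusters <- function(log_matrix, assignment, mm, zeta = 0.3,
                          n_random = 10000L, seed = 0L,
                          unknown_rule = "lambda_nonpos",
                          keep_null_samples = FALSE) {
  stopifnot(inherits(mm, "marker_matrix"))
  marker_expr <- log_matrix[mm$markers, , drop = FALSE]
  Y <- centroid_matrix(marker_expr, assignment)
  sup <- support_matrix(Y, zeta)
  V <- vote_matrix(mm$M_tilde, sup$Z_support)
  nd <- null_vote_distributions(marker_expr, assignment$sizes, mm$M_tilde,
                                zeta = zeta, n_random = n_random, seed = seed,
                                keep_samples = keep_null_samples)
  Lambda <- assignment_zscores(V, nd$null_mean, nd$null_std)
  tab <- assign_types(Lambda, mm$M, sup$Z_support, unknown_rule)
  ps_log("vote_clusters: labels = ", paste(tab$cell_type, collapse = ", "))
  structure(list(Y = Y, Z = sup$Z, Z_support = sup$Z_support, zeta = zeta,
                 V = V, degenerate = attr(V, "degenerate"),
                 null_mean = nd$null_mean, null_std = nd$null_std,
                 n_random = nd$n_random, Lambda = Lambda, table = tab,
                 types = mm$types, markers = mm$markers, M = mm$M,
                 null_samples = nd$samples),
            class = "vote_result")
}

#' Supporting markers of a cluster's assigned type
#'
#' @param result a `vote_result`.
#' @param cluster cluster index.
#' @return character vector of marker symbols both listed for the cluster's
#'   best type and supported in the cluster.
#' @export
supporting_markers <- function(result, cluster) {
  stopifnot(inherits(result, "vote_result"))
  k <- result$table$best_type[cluster]
  result$markers[result$M[k, ] == 1 & result$Z_support[, cluster] == 1]
}

#' @export
print.vote_result <- function(x, ...) {
  cat("vote_result:", length(x$types), "cell types x", ncol(x$V),
      "clusters; zeta =", x$zeta, "; null n =", x$n_random, "\n")
  print(x$table[, c("cluster", "cell_type", "max_lambda", "support_count",
                    "low_support")], row.names = FALSE)
  invisible(x)
}

#' Supported-marker counts across a threshold sweep
#'
#' Diagnostic for choosing `zeta`: reports, for each threshold in `zetas`,
#' the total number of supported (marker, cluster) pairs and the number of
#' supporting markers of each cluster's currently assigned type. The counts
#' are non-increasing in `zeta`; the working heuristic is to start at 0 and
#' raise `zeta` until the counts are almost constant.
#'
#' @param Y markers x clusters centroid matrix.
#' @param zetas thresholds to sweep (default `seq(0.1, 1.5, by = 0.1)`).
#' @return data frame with columns `zeta` and `n_supported`.
#' @export
zeta_sweep <- function(Y, zetas = seq(0.1, 1.5, by = 0.1)) {
  data.frame(zeta = zetas,
             n_supported = vapply(zetas, function(z)
               sum(support_matrix(Y, z)$Z_support), numeric(1)))
}
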