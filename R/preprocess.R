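#' Drop genes with no expression in any cell
#'
#' Keeps only genes expressed (value > 0) in at least one cell; the order of
#' surviving genes is preserved.
#'
#' @param x genes x cells expression matrix.
#' @return the filtered matrix.
#' @export
filter_expressed <- function(x) {
  check_expression(x)
  keep <- rowSums(x) > 0
  if (!any(keep)) stop("empty dataset: no gene is expressed in any cell")
  x[keep, , drop = FALSE]
}

#' Library-size normalization
#'
#' Divides each cell's expression vector by its total, so every column sums
#' to one. Equalizes sequencing yield differences between cells before the
#' log transform.
#'
#' @param x genes x cells matrix; every column must have a positive sum.
#' @return column-stochastic matrix of the same shape.
#' @export
normalize_counts <- function(x) {
  check_expression(x)
  cs <- colSums(x)
  if (any(cs <= 0))
    stop("cell(s) with zero total expression: ",
         paste(utils::head(colnames(x)[cs <= 0], 5), collapse = ", "))
  sweep(x, 2, cs, "/")
}

#' Log2 transform with zero replacement
#'
#' Applies `log2`, replacing all zeros by `m`, the smallest nonzero value of
#' the whole matrix, so dropouts map to the floor `log2(m)` rather than
#' minus infinity.
#'
#' @param x nonnegative matrix (normally the output of [normalize_counts()]).
#' @return list with `matrix` (log2 units) and `m`.
#' @export
log_transform <- function(x) {
  if (all(x == 0)) stop("all-zero matrix: nothing to transform")
  m <- min(x[x > 0])
  out <- x
  out[out == 0] <- m
  out <- log2(out)
  list(matrix = out, m = m)
}

#' Variance-based gene filter
#'
#' Flags genes whose expression standard deviation across cells is at least
#' `theta` times the mean standard deviation over all genes. `sigma` is the
#' population standard deviation (divide by the number of cells) of the
#' log-transformed expression.
#'
#' @param log_matrix genes x cells matrix in log2 units.
#' @param theta nonnegative variation threshold (default 0.3).
#' @return logical vector per gene, `TRUE` for genes passing the filter;
#'   carries attributes `sigma` and `sigma_mean`.
#' @export
variance_filter <- function(log_matrix, theta = 0.3) {
  if (ncol(log_matrix) < 2)
    stop("variance filter undefined for a single cell")
  if (theta < 0) stop("theta must be nonnegative")
  sigma <- row_pop_sd(log_matrix)
  sigma_mean <- mean(sigma)
  ratio <- if (sigma_mean > 0) sigma / sigma_mean else rep(0, length(sigma))
  mask <- ratio >= theta
  names(mask) <- rownames(log_matrix)
  attr(mask, "sigma") <- sigma
  attr(mask, "sigma_mean") <- sigma_mean
  mask
}

#' Preprocess an expression matrix
#'
#' Fixed pipeline: drop never-expressed genes, normalize each cell to total
#' one, log2-transform with zeros replaced by the global smallest nonzero
#' value `m`, then flag high-variation genes for clustering. The full
#' log-matrix (all expressed genes) is retained because marker voting uses
#' all expressed genes, not only the high-variation subset.
#'
#' @param x genes x cells matrix of raw counts or normalized expression.
#' @param theta variation threshold (default 0.3).
#' @return object of class `processed_expr`: `log_matrix`, logical
#'   `variable_gene_mask`, `m`, `sigma`, `sigma_mean`, `theta`.
#' @export
preprocess <- function(x, theta = 0.3) {
  check_expression(x)
  x <- filter_expressed(x)
  x <- normalize_counts(x)
  lt <- log_transform(x)
  mask <- variance_filter(lt$matrix, theta)
  ps_log("preprocess: ", nrow(lt$matrix), " expressed genes, ",
         sum(mask), " pass the variation filter (theta=", theta, ")")
  structure(list(log_matrix = lt$matrix,
                 variable_gene_mask = as.logical(mask),
                 m = lt$m,
                 sigma = attr(mask, "sigma"),
                 sigma_mean = attr(mask, "sigma_mean"),
                 theta = theta),
            class = "processed_expr")
}

#' @export
print.processed_expr <- function(x, ...) {
  cat("processed_expr:", nrow(x$log_matrix), "genes x", ncol(x$log_matrix),
      "cells;", sum(x$variable_gene_mask), "variable genes (theta=",
      x$theta, "), m =", signif(x$m, 4), "\n")
  invisible(x)
}
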