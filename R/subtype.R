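#' Recursive sub-typing of one major cell type
#'
#' Re-runs the complete pipeline on the cells previously assigned to one
#' major type, against a sub-type marker database. The raw expression
#' submatrix is re-processed from scratch (per-cell normalization, smallest
#' nonzero value, gene variances are all recomputed on the subset), the
#' number of sub-clusters is re-selected from the subset's own stability
#' curve, and sub-types with no expressed markers in the subset are discarded
#' before voting. Analyzing major types first and each of them separately is
#' deliberate: mixing major and sub-type markers in a single flat voting
#' round lets shared markers vote for the wrong candidates.
#'
#' @param expr the original genes x cells raw expression matrix.
#' @param parent_labels cell-type label per cell (character vector, named by
#'   barcode or aligned with `colnames(expr)`), e.g. `fit$cell_types`.
#' @param parent_type the major type whose cells are re-analyzed.
#' @param sub_db [marker_db()] of candidate sub-types.
#' @param min_cells refuse to sub-type fewer cells than this (default 50).
#' @param n_grid stability-curve grid for the subset (default 4:12).
#' @param ... further arguments passed to [run_pipeline()].
#' @return object of class `subtype_run`: `parent_type`, `parent_cells`,
#'   `fit` (the subset's `pollsort_fit`).
#' @export
run_subtype <- function(expr, parent_labels, parent_type, sub_db,
                        min_cells = 50L, n_grid = 4:12, ...) {
  check_expression(expr)
  if (!is.null(names(parent_labels)))
    parent_labels <- parent_labels[colnames(expr)]
  if (length(parent_labels) != ncol(expr))
    stop("parent_labels does not align with the expression columns")
  cells <- colnames(expr)[!is.na(parent_labels) & parent_labels == parent_type]
  if (length(cells) == 0)
    stop("no cell carries the parent type \"", parent_type, "\"")
  if (length(cells) < min_cells)
    stop("only ", length(cells), " \"", parent_type, "\" cells; at least ",
         min_cells, " required for sub-typing")
  ps_log("run_subtype: ", length(cells), " \"", parent_type, "\" cells")
  fit <- run_pipeline(expr[, cells, drop = FALSE], sub_db,
                      n_grid = n_grid, ...)
  structure(list(parent_type = parent_type, parent_cells = cells, fit = fit),
            class = "subtype_run")
}

#' @export
print.subtype_run <- function(x, ...) {
  cat("subtype_run of \"", x$parent_type, "\" (", length(x$parent_cells),
      " cells)\n", sep = "")
  print(x$fit)
  invisible(x)
}
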