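#' Construct a validated expression matrix
#'
#' The package's central container is a plain numeric matrix with genes in
#' rows (rownames = gene symbols, uppercased) and cells in columns
#' (colnames = barcodes). Values are nonnegative and finite; they may be raw
#' counts or already-normalized expression. Duplicate gene symbols are
#' collapsed by summation so that total signal per gene is preserved.
#'
#' @param values numeric matrix, genes x cells.
#' @param gene_ids character vector of gene symbols (length nrow(values)).
#'   Case-normalized to uppercase; duplicates summed with a warning.
#' @param cell_ids character vector of unique cell barcodes
#'   (length ncol(values)).
#' @return a numeric matrix with `gene_ids` rownames and `cell_ids` colnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("expression_matrix() needs gene_ids and cell_ids")
  gene_ids <- toupper(as.character(gene_ids))
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell barcodes: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop("expression values must be nonnegative; first offender: gene ",
         gene_ids[which(rowSums(values < 0) > 0)[1]])
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("summing ", length(dups), " duplicated gene symbol(s): ",
            paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ...")
    values <- rowsum(values, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(values)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  values
}

# internal sanity check used by pipeline entry points
check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric genes x cells matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and barcode colnames")
  if (any(x < 0) || any(!is.finite(x)))
    stop("expression values must be nonnegative and finite")
  invisible(x)
}
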