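#' Build the binary marker/cell-type matrix
#'
#' Restricts each cell type's markers to the genes actually expressed in the
#' dataset. Cell types whose markers are all unexpressed are dropped with a
#' warning; this is also how sub-type tables are pruned during recursive
#' analysis.
#'
#' @param db a [marker_db()].
#' @param expressed_genes character vector of expressed gene symbols (the
#'   rownames of the preprocessed log-matrix).
#' @return binary matrix `M` (cell types x markers) with dimnames; every row
#'   and every column contains at least one 1.
#' @export
build_marker_matrix <- function(db, expressed_genes) {
  stopifnot(inherits(db, "marker_db"))
  if (length(expressed_genes) == 0) stop("expressed gene set is empty")
  expressed_genes <- toupper(expressed_genes)
  kept <- lapply(db$markers_of, function(g) intersect(g, expressed_genes))
  dropped <- db$types[lengths(kept) == 0]
  if (length(dropped) == length(db$types))
    stop("no cell type has any expressed marker")
  if (length(dropped) > 0) {
    warning("dropping cell type(s) with no expressed marker: ",
            paste(dropped, collapse = ", "))
    kept <- kept[lengths(kept) > 0]
  }
  markers <- unique(unlist(kept, use.names = FALSE))
  M <- matrix(0, nrow = length(kept), ncol = length(markers),
              dimnames = list(names(kept), markers))
  for (k in names(kept)) M[k, kept[[k]]] <- 1
  M
}

#' Two-stage marker-weight normalization
#'
#' Converts the binary marker incidence matrix into voting weights:
#' first each row (cell type) is divided by its number of expressed markers,
#' so types with long marker lists get no head start; then each column
#' (marker) is divided by the number of cell types listing that marker, so a
#' marker private to one type keeps its full weight while shared markers are
#' diluted.
#'
#' @param M binary cell-types x markers matrix from [build_marker_matrix()].
#' @return nonnegative weight matrix `M_tilde` of the same shape; zero
#'   exactly where `M` is zero.
#' @export
normalize_marker_matrix <- function(M) {
  if (!all(M %in% c(0, 1))) stop("M must be binary")
  rs <- rowSums(M)
  cs <- colSums(M)
  if (any(rs == 0)) stop("cell type(s) with no marker: ",
                         paste(rownames(M)[rs == 0], collapse = ", "))
  if (any(cs == 0)) stop("marker(s) claimed by no cell type: ",
                         paste(colnames(M)[cs == 0], collapse = ", "))
  sweep(M / rs, 2, cs, "/")
}

#' Build binary and normalized marker matrices in one call
#'
#' @inheritParams build_marker_matrix
#' @return object of class `marker_matrix`: `M` (binary), `M_tilde`
#'   (normalized weights), `types`, `markers`.
#' @export
marker_matrix <- function(db, expressed_genes) {
  M <- build_marker_matrix(db, expressed_genes)
  structure(list(M = M, M_tilde = normalize_marker_matrix(M),
                 types = rownames(M), markers = colnames(M)),
            class = "marker_matrix")
}
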