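#' Read an expression matrix from disk
#'
#' Two layouts are supported:
#' \describe{
#'   \item{dense}{delimited text (TSV or CSV, chosen from the file extension
#'     or via `sep`), first column gene symbols, header row of cell barcodes.}
#'   \item{mtx}{MatrixMarket coordinate triplet (10x Cell Ranger v2 style)
#'     with companion `genes_path` (one symbol per line, or a two-column
#'     id/symbol TSV of which the second column is used) and `barcodes_path`
#'     (one barcode per line).}
#' }
#' Gene symbols are uppercased and duplicate rows are summed (with a warning).
#'
#' @param path path to the dense table or the `.mtx` file.
#' @param layout `"dense"` or `"mtx"`.
#' @param genes_path,barcodes_path companion files for `layout = "mtx"`.
#' @param sep field separator for the dense layout; default inferred from the
#'   extension (`","` for `.csv`, tab otherwise).
#' @param transpose set `TRUE` when a dense file has cells in rows.
#' @return numeric genes x cells matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, layout = c("dense", "mtx"),
                            genes_path = NULL, barcodes_path = NULL,
                            sep = NULL, transpose = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "dense") {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    if (length(header) < 2)
      stop("malformed header in ", path,
           ": expected gene column plus at least one barcode, got line: ",
           paste(header, collapse = sep))
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, row.names = NULL,
                             stringsAsFactors = FALSE, quote = "\"",
                             comment.char = "")
    ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric entries in dense expression file ", path)
    rownames(vals) <- ids
    if (transpose) vals <- t(vals)
    x <- expression_matrix(vals)
  } else {
    if (is.null(genes_path) || is.null(barcodes_path))
      stop("mtx layout needs genes_path and barcodes_path")
    m <- as.matrix(Matrix::readMM(path))
    gtab <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    genes <- if (ncol(gtab) >= 2) as.character(gtab[[2]]) else as.character(gtab[[1]])
    barcodes <- readLines(barcodes_path)
    x <- expression_matrix(m, gene_ids = genes, cell_ids = barcodes)
  }
  ps_log("read_expression: ", nrow(x), " genes x ", ncol(x), " cells from ", path)
  x
}

#' Read a marker/cell-type database from disk
#'
#' Two layouts:
#' \describe{
#'   \item{long}{two columns, `cell_type` then `gene`, one marker per row
#'     (header required, names irrelevant).}
#'   \item{wide}{binary gene x cell-type table: first column gene symbols,
#'     header of cell-type names, entries 0/1.}
#' }
#'
#' @param path delimited text file (`.csv` or tab-separated).
#' @param layout `"long"` or `"wide"`.
#' @param sep field separator; default inferred from the extension.
#' @return a [marker_db()] object.
#' @export
read_marker_database <- function(path, layout = c("long", "wide"), sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (layout == "long") {
    if (ncol(tab) < 2)
      stop("long marker layout needs two columns (cell_type, gene) in ", path)
    types <- as.character(tab[[1]])
    genes <- as.character(tab[[2]])
    keep <- nzchar(types) & nzchar(genes) & !is.na(types) & !is.na(genes)
    if (!all(keep))
      stop("empty cell type or gene field at line(s) ",
           paste(which(!keep) + 1L, collapse = ", "), " of ", path)
    db <- marker_db(split(genes, factor(types, levels = unique(types))))
  } else {
    if (ncol(tab) < 2)
      stop("wide marker layout needs a gene column plus cell-type columns in ", path)
    genes <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(mat) || !all(mat %in% c(0, 1)))
      stop("wide marker table must be binary 0/1; offending value(s) in ", path)
    lists <- lapply(colnames(mat), function(k) genes[mat[, k] == 1])
    names(lists) <- colnames(mat)
    db <- marker_db(lists)
  }
  ps_log("read_marker_database: ", length(db$types), " cell types from ", path)
  db
}

# full-precision delimited matrix writer (round-trips to < 1e-12)
write_matrix_tsv <- function(m, path) {
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  utils::write.table(fm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read back a matrix written by [write_results()]
#' @param path tab-separated matrix file with row and column names.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Write pipeline results as delimited text
#'
#' Writes four files to `out_dir`: `cells.tsv` (barcode, cluster, cell_type),
#' `lambda.tsv` (significance z-scores, types x clusters), `votes.tsv`
#' (approval scores, types x clusters) and `supporting_markers.tsv`
#' (cluster, cell_type, marker; one supporting marker per row).
#'
#' @param result a `vote_result` (see [vote_clusters()]).
#' @param assignment a `cluster_assignment` (see [cluster_cells()]).
#' @param out_dir output directory, created if absent.
#' @return (invisibly) named vector of the files written.
#' @export
write_results <- function(result, assignment, out_dir) {
  stopifnot(inherits(result, "vote_result"),
            inherits(assignment, "cluster_assignment"))
  if (assignment$n < 1 || ncol(result$Lambda) != assignment$n)
    stop("result and assignment disagree on the cluster set (",
         ncol(result$Lambda), " vs ", assignment$n, " clusters)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir)

  cells <- data.frame(barcode = names(assignment$labels),
                      cluster = unname(assignment$labels),
                      cell_type = result$table$cell_type[assignment$labels],
                      stringsAsFactors = FALSE)
  f_cells <- file.path(out_dir, "cells.tsv")
  utils::write.table(cells, f_cells, sep = "\t", quote = FALSE, row.names = FALSE)

  f_lambda <- file.path(out_dir, "lambda.tsv")
  write_matrix_tsv(result$Lambda, f_lambda)
  f_votes <- file.path(out_dir, "votes.tsv")
  write_matrix_tsv(result$V, f_votes)

  sup <- do.call(rbind, lapply(seq_len(assignment$n), function(c) {
    mk <- supporting_markers(result, c)
    if (length(mk) == 0) return(NULL)
    data.frame(cluster = c, cell_type = result$table$cell_type[c], marker = mk,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sup))
    sup <- data.frame(cluster = integer(), cell_type = character(),
                      marker = character())
  f_sup <- file.path(out_dir, "supporting_markers.tsv")
  utils::write.table(sup, f_sup, sep = "\t", quote = FALSE, row.names = FALSE)

  ps_log("write_results: 4 files in ", out_dir)
  invisible(c(cells = f_cells, lambda = f_lambda, votes = f_votes,
              supporting_markers = f_sup))
}
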