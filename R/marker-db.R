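#' Construct a marker/cell-type database
#'
#' A marker database maps cell-type names to sets of marker gene symbols.
#' Gene symbols are uppercased; marker matching downstream is exact string
#' equality after this normalization (no alias resolution).
#'
#' @param markers_of named list: cell type -> character vector of marker gene
#'   symbols. Every type must have at least one marker.
#' @return object of class `marker_db` with elements `types` (ordered type
#'   names) and `markers_of` (named list of unique uppercase symbols).
#' @export
marker_db <- function(markers_of) {
  if (!is.list(markers_of) || is.null(names(markers_of)) ||
      any(!nzchar(names(markers_of))))
    stop("markers_of must be a named list of marker gene vectors")
  if (anyDuplicated(names(markers_of)))
    stop("duplicate cell-type names in marker database")
  markers_of <- lapply(markers_of, function(g) {
    g <- toupper(as.character(g))
    g <- unique(g[!is.na(g) & nzchar(g)])
    g
  })
  empty <- names(markers_of)[lengths(markers_of) == 0]
  if (length(empty) > 0)
    stop("cell type(s) with zero markers: ", paste(empty, collapse = ", "))
  structure(list(types = names(markers_of), markers_of = markers_of),
            class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat("marker_db:", length(x$types), "cell types,",
      length(unique(unlist(x$markers_of))), "distinct markers\n")
  for (k in x$types)
    cat("  ", k, ": ", paste(utils::head(x$markers_of[[k]], 8), collapse = ", "),
        if (length(x$markers_of[[k]]) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
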