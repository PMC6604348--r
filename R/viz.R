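utils::globalVariables(c("tSNE1", "tSNE2", "cluster", "marker", "value",
                         "expression", "expressing", "cell_type", "n",
                         "mean_ari", "sd_ari", "fraction", "sample_id",
                         "size", "ypos"))

#' Deterministic cell-type palette
#'
#' Assigns each type a fixed color keyed by its (sorted) name so that the
#' same type has the same color across samples and figures; `"Unknown"` is
#' always grey.
#'
#' @param types character vector of cell-type names.
#' @return named vector of hex colors.
#' @export
type_palette <- function(types) {
  types <- sort(unique(setdiff(types, "Unknown")))
  base <- grDevices::hcl(h = seq(15, 375, length.out = max(length(types), 2) + 1),
                         c = 100, l = 62)[seq_along(types)]
  c(stats::setNames(base, types), Unknown = "grey60")
}

#' t-SNE layout colored by cluster or cell type
#'
#' @param coords cells x 2 coordinate matrix from [tsne_layout()].
#' @param labels per-cell cluster indices or cell-type names.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_embedding <- function(coords, labels, title = "t-SNE layout") {
  df <- data.frame(tSNE1 = coords[, 1], tSNE2 = coords[, 2],
                   label = as.factor(labels))
  p <- ggplot2::ggplot(df, ggplot2::aes(tSNE1, tSNE2, colour = label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = title, colour = NULL) +
    ggplot2::theme_minimal()
  if (all(as.character(unique(labels)) %in%
          names(type_palette(as.character(labels)))))
    p <- p + ggplot2::scale_colour_manual(values = type_palette(as.character(labels)))
  p
}

#' Marker expression overlaid on the layout
#'
#' Cells expressing the marker (above the dataset's log floor) are drawn as
#' stars and color-scaled by expression; non-expressing cells are light dots.
#'
#' @param coords cells x 2 coordinate matrix.
#' @param expr_vector per-cell log expression of one marker.
#' @param marker marker name, used as the title.
#' @param floor values <= this are "not expressing" (default: the minimum).
#' @return a ggplot object.
#' @export
plot_marker_overlay <- function(coords, expr_vector, marker = "marker",
                                floor = min(expr_vector)) {
  df <- data.frame(tSNE1 = coords[, 1], tSNE2 = coords[, 2],
                   expression = expr_vector,
                   expressing = expr_vector > floor)
  ggplot2::ggplot(df, ggplot2::aes(tSNE1, tSNE2)) +
    ggplot2::geom_point(data = df[!df$expressing, ], colour = "grey80",
                        size = 0.6) +
    ggplot2::geom_point(data = df[df$expressing, ],
                        ggplot2::aes(colour = expression),
                        shape = 8, size = 1.4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = marker) +
    ggplot2::theme_minimal()
}

#' Marker-centroid heatmap with support stars
#'
#' Shows the mean expression of each marker per cluster; supported markers
#' (z-score at or above the threshold) carry a star, colored red when the
#' marker supports the cluster's assigned type.
#'
#' @param result a `vote_result`.
#' @return a ggplot object.
#' @export
plot_marker_centroid_heatmap <- function(result) {
  stopifnot(inherits(result, "vote_result"))
  Y <- result$Y
  df <- data.frame(marker = rep(rownames(Y), ncol(Y)),
                   cluster = rep(colnames(Y), each = nrow(Y)),
                   value = as.vector(Y),
                   support = as.vector(result$Z_support) == 1)
  df$supports_assigned <- df$support &
    result$M[cbind(match(result$table$best_type[as.integer(df$cluster)],
                         rownames(result$M)),
                   match(df$marker, result$markers))] == 1
  df$marker <- factor(df$marker, levels = rev(rownames(Y)))
  lab <- paste0(result$table$cell_type, " (", result$table$cluster, ")")
  df$cluster <- factor(lab[as.integer(df$cluster)], levels = lab)
  ggplot2::ggplot(df, ggplot2::aes(cluster, marker, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$support & !df$supports_assigned, ],
                        shape = 8, colour = "black", size = 1.6) +
    ggplot2::geom_point(data = df[df$supports_assigned, ],
                        shape = 8, colour = "red", size = 1.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "navy") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Voting significance matrix with cluster-size bars
#'
#' Heatmap of the significance z-scores, masking non-positive values; rows
#' are clusters named by their assigned type (low-support clusters flagged
#' with `*`), with a side barplot of relative and absolute cluster sizes.
#'
#' @param result a `vote_result`.
#' @param assignment the matching `cluster_assignment`.
#' @return a patchwork of two ggplot objects.
#' @export
plot_voting_matrix <- function(result, assignment) {
  stopifnot(inherits(result, "vote_result"),
            inherits(assignment, "cluster_assignment"))
  L <- result$Lambda
  flag <- ifelse(result$table$low_support, "*", "")
  row_lab <- paste0(result$table$cell_type, " (", result$table$cluster - 1, ")",
                    flag)
  df <- data.frame(cell_type = rep(rownames(L), ncol(L)),
                   cluster = rep(row_lab, each = nrow(L)),
                   value = as.vector(L))
  df$value[df$value <= 0] <- NA       # negative z-scores are not shown
  df$cluster <- factor(df$cluster, levels = rev(row_lab))
  heat <- ggplot2::ggplot(df, ggplot2::aes(cell_type, cluster, fill = value)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_gradient(low = "mistyrose", high = "darkred",
                                 na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  sz <- data.frame(cluster = factor(row_lab, levels = rev(row_lab)),
                   size = assignment$sizes)
  sz$fraction <- 100 * sz$size / sum(sz$size)
  bars <- ggplot2::ggplot(sz, ggplot2::aes(fraction, cluster)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%% (%d)", fraction,
                                                    size)),
                       hjust = -0.05, size = 2.8) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.35))) +
    ggplot2::labs(x = "% of cells", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  patchwork::wrap_plots(heat, bars, widths = c(3, 1))
}

#' Null score distributions per cell type
#'
#' One panel per cell type showing the random-cluster null distribution of
#' the approval score for each cluster, with the observed score as a vertical
#' line. Requires the fit to have kept the null samples
#' (`keep_null_samples = TRUE`).
#'
#' @param result a `vote_result` carrying `null_samples`.
#' @param types subset of types to show (default: all).
#' @return a ggplot object (faceted by cell type).
#' @export
plot_null_histograms <- function(result, types = result$types) {
  stopifnot(inherits(result, "vote_result"))
  if (is.null(result$null_samples))
    stop("fit was run without keep_null_samples = TRUE")
  s <- result$null_samples
  K <- dim(s)[1]; C <- dim(s)[2]; R <- dim(s)[3]
  df <- data.frame(cell_type = rep(result$types, times = C * R),
                   cluster = factor(rep(rep(seq_len(C), each = K), times = R)),
                   value = as.vector(s))
  df <- df[df$cell_type %in% types, ]
  obs <- data.frame(cell_type = rep(rownames(result$V), ncol(result$V)),
                    cluster = factor(rep(seq_len(C), each = K)),
                    value = as.vector(result$V))
  obs <- obs[obs$cell_type %in% types, ]
  ggplot2::ggplot(df, ggplot2::aes(value, fill = cluster)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = value, colour = cluster),
                        linetype = 2) +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = "approval score", y = "count") +
    ggplot2::theme_minimal()
}

#' Cell-type composition barplot
#'
#' Stacked per-sample cell-type fractions, types ordered by their average
#' fraction with `"Unknown"` always placed last.
#'
#' @param fractions data frame with columns `sample_id`, `cell_type`,
#'   `fraction` (fractions per sample summing to 1 or 100).
#' @return a ggplot object.
#' @export
plot_fraction_barplot <- function(fractions) {
  stopifnot(all(c("sample_id", "cell_type", "fraction") %in% names(fractions)))
  avg <- tapply(fractions$fraction, fractions$cell_type, mean)
  ord <- names(sort(avg, decreasing = TRUE))
  ord <- c(setdiff(ord, "Unknown"),
           if ("Unknown" %in% ord) "Unknown")
  fractions$cell_type <- factor(fractions$cell_type, levels = ord)
  ggplot2::ggplot(fractions,
                  ggplot2::aes(sample_id, fraction, fill = cell_type)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = type_palette(levels(fractions$cell_type))) +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Cluster-number stability curve plot
#'
#' @param curve an `ari_curve`.
#' @param selected optionally, the selected `n` to mark.
#' @return a ggplot object.
#' @export
plot_ari_curve <- function(curve, selected = NULL) {
  stopifnot(inherits(curve, "ari_curve"))
  df <- curve$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(n, mean_ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_ari - sd_ari,
                                          ymax = mean_ari + sd_ari)) +
    ggplot2::labs(x = "number of clusters n", y = "mean ARI") +
    ggplot2::theme_minimal()
  if (!is.null(selected))
    p <- p + ggplot2::geom_vline(xintercept = selected, linetype = 2,
                                 colour = "red")
  p
}

#' Write a figure to disk
#'
#' @param plot a ggplot/patchwork object.
#' @param path output file; format from the extension (png or svg).
#' @param width,height,dpi passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render <- function(plot, path, width = 7, height = 5, dpi = 150) {
  if (!grepl("\\.(png|svg)$", path, ignore.case = TRUE))
    stop("supported output formats: png, svg")
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
  invisible(path)
}
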