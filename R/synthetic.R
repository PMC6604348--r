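#' Synthetic expression data with planted cell types
#'
#' Generates a genes x cells count matrix with known ground truth, standing
#' in for droplet scRNA-seq data in tests and examples. Counts are
#' overdispersed (gamma-mixed Poisson, i.e. negative binomial) around
#' gene-specific means; background genes share a lognormal mean profile and
#' every cell carries a lognormal size factor, so library-size normalization
#' is non-trivial. Each planted type owns `markers_per_type` private marker
#' genes whose mean is multiplied by `fold_change` inside the owning type.
#' Every entry is then independently zeroed with probability `dropout_rate`,
#' emulating transcripts that go undetected although expressed.
#'
#' @param n_types number of planted cell types (default 4).
#' @param cells_per_type cells per type (default 200).
#' @param markers_per_type private markers per type (default 5).
#' @param n_background_genes unstructured genes (default 500).
#' @param fold_change marker mean multiplier in the owning type, > 1
#'   (default 8).
#' @param dropout_rate per-entry zeroing probability in [0, 1) (default 0.5).
#' @param seed RNG seed; the dataset is a deterministic function of it.
#' @param dispersion negative-binomial dispersion (1/size; default 0.1).
#' @param marker_base_mean baseline marker mean count (default 0.5).
#' @param size_factor_sdlog lognormal sdlog of per-cell size factors
#'   (default 0.3).
#' @return list with `expr` (genes x cells count matrix), `db` (the
#'   [marker_db()] of planted markers), and `truth` (class
#'   `synthetic_truth`: `true_type` per cell, `planted_markers`,
#'   `fold_change`, `dropout_rate`, `n_background_genes`, `seed`).
#' @export
generate_dataset <- function(n_types = 4L, cells_per_type = 200L,
                             markers_per_type = 5L, n_background_genes = 500L,
                             fold_change = 8, dropout_rate = 0.5, seed = 0L,
                             dispersion = 0.1, marker_base_mean = 0.5,
                             size_factor_sdlog = 0.3) {
  if (n_types < 1 || cells_per_type < 1 || markers_per_type < 1 ||
      n_background_genes < 1)
    stop("all counts must be >= 1")
  if (fold_change <= 1) stop("fold_change must be > 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")

  types <- sprintf("TYPE%d", seq_len(n_types))
  true_type <- rep(types, each = cells_per_type)
  planted <- lapply(seq_len(n_types), function(t)
    sprintf("MK%d_%d", t, seq_len(markers_per_type)))
  names(planted) <- types

  withr::with_seed(seed, {
    expr <- simulate_counts(true_type, planted, n_background_genes,
                            fold_change, dropout_rate, dispersion,
                            marker_base_mean, size_factor_sdlog)
  })
  truth <- structure(list(true_type = stats::setNames(true_type, colnames(expr)),
                          planted_markers = planted,
                          fold_change = fold_change,
                          dropout_rate = dropout_rate,
                          n_background_genes = as.integer(n_background_genes),
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(expr = expr, db = marker_db(planted), truth = truth)
}

# shared count simulator: `owner` maps marker gene -> the per-cell group
# label in whose cells its mean is multiplied by fold_change; `group` labels
# may be compound ("A|B", cell belongs to both groups)
simulate_counts <- function(group, planted, n_background_genes, fold_change,
                            dropout_rate, dispersion, marker_base_mean,
                            size_factor_sdlog) {
  n_cells <- length(group)
  bg_genes <- sprintf("BG%04d", seq_len(n_background_genes))
  marker_genes <- unlist(planted, use.names = FALSE)
  owner <- rep(names(planted), times = lengths(planted))
  genes <- c(bg_genes, marker_genes)

  bg_mu <- stats::rlnorm(n_background_genes, meanlog = log(0.1), sdlog = 0.5)
  sf <- stats::rlnorm(n_cells, meanlog = 0, sdlog = size_factor_sdlog)
  mu <- matrix(0, length(genes), n_cells, dimnames = list(genes, NULL))
  mu[bg_genes, ] <- outer(bg_mu, sf)
  groups <- strsplit(group, "|", fixed = TRUE)
  owns <- vapply(seq_along(owner), function(m)
    vapply(groups, function(g) owner[m] %in% g, logical(1)),
    logical(n_cells))
  fold <- 1 + (fold_change - 1) * t(owns)
  mu[marker_genes, ] <- marker_base_mean * fold * rep(sf, each = length(marker_genes))

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu))
  if (dropout_rate > 0)
    counts <- counts * (matrix(stats::runif(length(counts)), nrow = nrow(counts))
                        >= dropout_rate)
  dimnames(counts) <- list(genes, sprintf("CELL%05d", seq_len(n_cells)))
  expression_matrix(counts)
}

#' Synthetic data with planted sub-types inside one major type
#'
#' Extends [generate_dataset()] with a two-level truth: major types each own
#' private major markers, and the cells of the first major type are further
#' split into sub-types owning private sub-markers. Used to exercise the
#' recursive sub-typing analysis.
#'
#' @param n_major number of major types (default 2).
#' @param cells_per_major cells per major type (default 240).
#' @param n_sub number of sub-types inside the first major type (default 3).
#' @param markers_per_type private markers per (major or sub) type
#'   (default 5).
#' @inheritParams generate_dataset
#' @return list with `expr`, `major_db`, `sub_db`, and `truth` holding
#'   `major_type` and `sub_type` per cell (`sub_type` is `NA` outside the
#'   first major type).
#' @export
generate_subtyped_dataset <- function(n_major = 2L, cells_per_major = 240L,
                                      n_sub = 3L, markers_per_type = 5L,
                                      n_background_genes = 500L,
                                      fold_change = 8, dropout_rate = 0.3,
                                      seed = 0L, dispersion = 0.1,
                                      marker_base_mean = 0.5,
                                      size_factor_sdlog = 0.3) {
  if (n_major < 2 || n_sub < 2) stop("need >= 2 major types and >= 2 sub-types")
  if (cells_per_major %% n_sub != 0)
    cells_per_major <- n_sub * ceiling(cells_per_major / n_sub)
  majors <- sprintf("MAJOR%d", seq_len(n_major))
  subs <- sprintf("SUB%d", seq_len(n_sub))
  major_lab <- rep(majors, each = cells_per_major)
  sub_lab <- rep(NA_character_, length(major_lab))
  sub_lab[major_lab == majors[1]] <- rep(subs, each = cells_per_major / n_sub)

  planted_major <- lapply(seq_len(n_major), function(t)
    sprintf("MJ%d_%d", t, seq_len(markers_per_type)))
  names(planted_major) <- majors
  planted_sub <- lapply(seq_len(n_sub), function(t)
    sprintf("SB%d_%d", t, seq_len(markers_per_type)))
  names(planted_sub) <- subs

  # every cell belongs to its major group and (inside the first major type)
  # also to its sub group: major markers fold across the whole major type,
  # sub markers only inside their sub-group
  group <- ifelse(is.na(sub_lab), major_lab,
                  paste(major_lab, sub_lab, sep = "|"))
  planted <- c(planted_major, planted_sub)
  withr::with_seed(seed, {
    expr <- simulate_counts(group, planted, n_background_genes, fold_change,
                            dropout_rate, dispersion, marker_base_mean,
                            size_factor_sdlog)
  })

  truth <- structure(list(major_type = stats::setNames(major_lab, colnames(expr)),
                          sub_type = stats::setNames(sub_lab, colnames(expr)),
                          planted_markers = planted,
                          fold_change = fold_change,
                          dropout_rate = dropout_rate,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(expr = expr, major_db = marker_db(planted_major),
       sub_db = marker_db(planted_sub), truth = truth)
}
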