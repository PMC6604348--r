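make_assignment <- function(labels) {
  labels <- as.integer(labels)
  n <- max(labels)
  structure(list(labels = stats::setNames(labels,
                                          paste0("c", seq_along(labels))),
                 n = n, sizes = as.integer(tabulate(labels, n))),
            class = "cluster_assignment")
}

test_that("centroid matrix averages marker expression per cluster", {
  me <- matrix(c(2, 4, 1,
                 0, 0, 9), 2, 3, byrow = TRUE,
               dimnames = list(c("m1", "m2"), paste0("c", 1:3)))
  a <- make_assignment(c(1, 1, 2))
  Y <- centroid_matrix(me, a)
  expect_equal(unname(Y), matrix(c(3, 1, 0, 9), 2, 2, byrow = TRUE))
  # singleton cluster reproduces its own expression; constant marker is flat
  expect_equal(unname(Y[, 2]), unname(me[, 3]))
})

test_that("support z-scores use the population sd across clusters", {
  Y <- matrix(c(0, 0, 10), 1, 3)
  s <- support_matrix(Y, zeta = 0.3)
  expect_equal(unname(s$Z[1, ]), c(-1 / sqrt(2), -1 / sqrt(2), sqrt(2)))
  expect_equal(unname(s$Z_support[1, ]), c(0, 0, 1))
  # constant row carries no support
  s2 <- support_matrix(matrix(5, 1, 3), zeta = 0.3)
  expect_equal(unname(s2$Z[1, ]), c(0, 0, 0))
  expect_equal(sum(s2$Z_support), 0)
  # as zeta -> -Inf everything becomes supported
  expect_equal(sum(support_matrix(Y, zeta = -100)$Z_support), 3)
  expect_error(support_matrix(Y[, 1, drop = FALSE]), "single cluster")
})

test_that("vote matrix matches the worked example and normalizes columns", {
  M_tilde <- matrix(c(0.5, 0.25, 0, 0.5), 2, 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("g1", "g2")))
  Zs <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "1"))
  V <- vote_matrix(M_tilde, Zs)
  expect_equal(unname(V[, 1]), c(0.6, 0.4))

  # single cell type: every supported cluster votes 1
  V1 <- vote_matrix(matrix(c(0.5, 0.5), 1, 2), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(unname(V1), matrix(1, 1, 2), ignore_attr = TRUE)

  # no supported marker: zero column, flagged
  V0 <- vote_matrix(M_tilde, matrix(0, 2, 1))
  expect_equal(unname(V0[, 1]), c(0, 0))
  expect_true(attr(V0, "degenerate"))
  expect_error(vote_matrix(M_tilde, matrix(1, 3, 1)), "marker axes")
})

test_that("vote matrix equals the brute-force double-loop oracle", {
  withr::with_seed(41, {
    for (i in 1:20) {
      K <- sample(2:5, 1); M <- sample(4:20, 1); C <- sample(2:6, 1)
      Mt <- normalize_marker_matrix(random_marker_M(K, M))
      Zs <- matrix(stats::rbinom(M * C, 1, 0.5), M, C)
      V <- vote_matrix(Mt, Zs)
      expect_lt(max(abs(V - vote_oracle(Mt, Zs))), 1e-12)
      ok <- !attr(V, "degenerate")
      if (any(ok))
        expect_lt(max(abs(colSums(V[, ok, drop = FALSE]) - 1)), 1e-12)
    }
  })
})

test_that("supported markers shrink monotonically as zeta grows", {
  withr::with_seed(42, {
    me <- matrix(stats::rnorm(15 * 40), 15, 40,
                 dimnames = list(paste0("m", 1:15), paste0("c", 1:40)))
  })
  Y <- centroid_matrix(me, make_assignment(rep(1:4, each = 10)))
  prev <- NULL
  for (z in seq(0.1, 1.5, by = 0.1)) {
    cur <- support_matrix(Y, z)$Z_support
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("null distributions are seeded, size-checked, and match a literal replay", {
  withr::with_seed(43, {
    me <- matrix(stats::rnorm(6 * 30), 6, 30,
                 dimnames = list(paste0("m", 1:6), paste0("c", 1:30)))
  })
  Mt <- normalize_marker_matrix(random_marker_M(3, 6))
  nd <- null_vote_distributions(me, c(10, 12, 8), Mt, zeta = 0.3,
                                n_random = 40, seed = 5, chunk = 7)
  nd2 <- null_vote_distributions(me, c(10, 12, 8), Mt, zeta = 0.3,
                                 n_random = 40, seed = 5, chunk = 40)
  expect_equal(nd$null_mean, nd2$null_mean, tolerance = 1e-12)
  expect_equal(nd$null_std, nd2$null_std, tolerance = 1e-12)

  # literal per-replicate recomputation of steps (i)-(ii), same RNG stream
  sizes <- c(10, 12, 8)
  Vs <- withr::with_seed(5, {
    replicate(40, {
      perm <- sample.int(30)
      lab <- integer(30)
      lab[perm] <- rep(seq_along(sizes), times = sizes)
      Y <- centroid_matrix(me, make_assignment(lab))
      vote_matrix(Mt, support_matrix(Y, 0.3)$Z_support)
    })
  })
  expect_equal(nd$null_mean, apply(Vs, c(1, 2), mean),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nd$null_std,
               apply(Vs, c(1, 2), function(v) sqrt(mean((v - mean(v))^2))),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(null_vote_distributions(me, c(10, 10), Mt, n_random = 10),
               "cells")
  expect_error(null_vote_distributions(me, c(15, 15), Mt, n_random = 1),
               "n_random")
})

test_that("assignment z-scores center, scale, and apply the sentinel rule", {
  V <- matrix(c(0.5, 0.7), 1, 2)
  mu <- matrix(c(0.5, 0.5), 1, 2)
  sd_ <- matrix(c(0.1, 0.2), 1, 2)
  L <- assignment_zscores(V, mu, sd_)
  expect_equal(unname(L), matrix(c(0, 1), 1, 2))
  # zero-spread nulls: 0 when equal, signed sentinel otherwise
  L2 <- assignment_zscores(matrix(c(0.5, 0.7, 0.3), 1, 3),
                           matrix(0.5, 1, 3), matrix(0, 1, 3))
  expect_equal(unname(L2), matrix(c(0, 1e9, -1e9), 1, 3))
})

test_that("type assignment takes the argmax, counts support, and flags Unknown", {
  L <- matrix(c(3, 1, -2, -1), 2, 2,
              dimnames = list(c("A", "B"), NULL))
  M <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("g", 1:4)))
  Zs <- matrix(c(1, 1, 1, 0,
                 0, 0, 0, 0), 4, 2)
  tab <- assign_types(L, M, Zs)
  expect_equal(tab$cell_type, c("A", "Unknown"))
  expect_equal(tab$best_type, c("A", "B"))   # -1 beats -2 in column 2
  expect_equal(tab$support_count, c(3L, 0L))
  expect_true(all(tab$low_support))

  # the Unknown rule can be switched off, restoring the raw argmax label
  tab2 <- assign_types(L, M, Zs, unknown_rule = "off")
  expect_equal(tab2$cell_type, c("A", "B"))

  # argmax tie: first type in declared order wins
  Lt <- matrix(c(2, 2), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(assign_types(Lt, M, matrix(1, 4, 1))$cell_type, "A")
})

test_that("null calibration: scores from structureless data standardize to ~N(0,1)", {
  # i.i.d. cells, arbitrary fixed-size partition: the observed vote is one
  # draw from its own null, so Lambda pooled over data replicates has mean
  # ~0 and sd ~1 (small replicate count here; the acceptance suite runs the
  # full-size version)
  Mt <- normalize_marker_matrix(random_marker_M(3, 10))
  lambdas <- withr::with_seed(44, {
    unlist(lapply(1:12, function(i) {
      me <- matrix(stats::rnorm(10 * 60), 10, 60,
                   dimnames = list(colnames(Mt), paste0("c", 1:60)))
      a <- make_assignment(rep(1:3, each = 20))
      Y <- centroid_matrix(me, a)
      V <- vote_matrix(Mt, support_matrix(Y, 0.3)$Z_support)
      nd <- null_vote_distributions(me, a$sizes, Mt, zeta = 0.3,
                                    n_random = 500, seed = i)
      L <- assignment_zscores(V, nd$null_mean, nd$null_std)
      L[abs(L) < 1e8]
    }))
  })
  expect_lt(abs(mean(lambdas)), 0.25)
  expect_gt(stats::sd(lambdas), 0.7)
  expect_lt(stats::sd(lambdas), 1.3)
})

test_that("vote_clusters wires the stages together end to end", {
  d <- generate_dataset(n_types = 2, cells_per_type = 40,
                        n_background_genes = 60, dropout_rate = 0.2, seed = 9)
  proc <- preprocess(d$expr)
  red <- suppressWarnings(pca_reduce(
    proc$log_matrix[proc$variable_gene_mask, , drop = FALSE], 100))
  a <- cluster_cells(red, 2)
  mm <- marker_matrix(d$db, rownames(proc$log_matrix))
  vr <- vote_clusters(proc$log_matrix, a, mm, n_random = 300, seed = 9)
  expect_s3_class(vr, "vote_result")
  expect_equal(dim(vr$V), c(2, 2))
  ok <- !vr$degenerate
  expect_lt(max(abs(colSums(vr$V[, ok, drop = FALSE]) - 1)), 1e-12)
  expect_equal(sort(vr$table$cell_type), c("TYPE1", "TYPE2"))
  for (cl in 1:2)
    expect_equal(length(supporting_markers(vr, cl)),
                 vr$table$support_count[cl])
})
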