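test_that("ARI satisfies identity, label invariance, and the singleton case", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(7, 7, 5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  expect_error(adjusted_rand_index(a, a[-1]), "different lengths")
})

test_that("ARI matches the brute-force pair-counting oracle", {
  withr::with_seed(5, {
    for (i in 1:25) {
      n <- sample(8:50, 1)
      a <- sample(1:4, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b))
      # permutation invariance under random relabeling
      perm <- sample(max(a))
      expect_equal(adjusted_rand_index(perm[a], b),
                   adjusted_rand_index(a, b))
    }
  })
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- sample(1:5, 40, replace = TRUE)
      b <- sample(1:4, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("PCA respects rank and dimension bounds", {
  # rank-1 matrix: one informative component
  base <- matrix(stats::rnorm(20), 20, 1,
                 dimnames = list(paste0("g", 1:20), NULL))
  x <- base %*% t(seq(1, 2, length.out = 6))
  colnames(x) <- paste0("c", 1:6)
  suppressWarnings(red <- pca_reduce(x, k = 100))
  expect_lte(red$k_pc, 5)
  v <- apply(red$components, 1, stats::var)
  expect_gt(v[1] / sum(v), 1 - 1e-10)

  expect_warning(red2 <- pca_reduce(x, k = 100), "available")
  expect_error(pca_reduce(x[, 1, drop = FALSE]), "2 cells")
})

test_that("PCA scores are rotation-invariant up to pairwise distances", {
  withr::with_seed(21, {
    x <- matrix(stats::rnorm(30 * 12), 30, 12,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:12)))
    q <- qr.Q(qr(matrix(stats::rnorm(900), 30, 30)))
  })
  d1 <- dist(t(pca_reduce(x, k = 5)$components))
  d2 <- dist(t(pca_reduce(q %*% x, k = 5)$components))
  expect_lt(max(abs(d1 - d2)), 1e-8)
})

test_that("stability curve compares the expected number of partition pairs", {
  red <- cloud_reduced(n_per = 15, k = 2)
  cu <- ari_curve(red, n_values = 2:4, reps_per_run = 12, n_runs = 2,
                  seed = 3, n_iter = 10)
  expect_equal(cu$n_pairs, 66)
  cu2 <- ari_curve(red, n_values = 2:4, reps_per_run = 2, n_runs = 2,
                   seed = 3, n_iter = 10)
  expect_equal(cu2$n_pairs, 1)
  expect_true(all(is.finite(cu2$curve$mean_ari)))
  expect_error(ari_curve(red, n_values = c(2, 1000)), "larger than")
})

test_that("stability peaks at the true number of separated clouds", {
  red <- cloud_reduced(n_per = 25, k = 3, sep = 25)
  cu <- ari_curve(red, n_values = 2:6, reps_per_run = 4, n_runs = 6,
                  seed = 9, n_iter = 40)
  m <- cu$curve$mean_ari
  expect_gt(m[cu$curve$n == 3], 0.95)
  # determinism given the seed
  cu2 <- ari_curve(red, n_values = 2:6, reps_per_run = 4, n_runs = 6,
                   seed = 9, n_iter = 40)
  expect_identical(cu$curve, cu2$curve)
})

test_that("select_n applies the first-peak-from-the-right rule", {
  mk <- function(n, m) structure(list(curve = data.frame(n = n, mean_ari = m)),
                                 class = "ari_curve")
  expect_equal(select_n(mk(4:8, c(0.95, 0.60, 0.80, 0.70, 0.65))), 6)
  # strictly decreasing: fallback argmax excluding the smallest n
  expect_equal(select_n(mk(4:8, c(0.9, 0.8, 0.7, 0.6, 0.5))), 5)
  # single interior peak at the high end
  expect_equal(select_n(mk(4:9, c(0.5, 0.45, 0.4, 0.42, 0.6, 0.3))), 8)
  # adjacent tie: the larger n wins (scan arrives there first)
  expect_equal(select_n(mk(4:8, c(0.9, 0.5, 0.7, 0.7, 0.4))), 7)
  expect_warning(sel <- select_n(mk(4:8, rep(0.5, 5))), "flat")
  expect_equal(sel, 8)
  expect_error(select_n(mk(4:5, c(0.2, 0.3))), "3 grid points")
})

test_that("agglomerative clustering recovers planted clouds and is deterministic", {
  red <- cloud_reduced(n_per = 30, k = 3, sep = 25)
  a <- cluster_cells(red, 3)
  expect_equal(adjusted_rand_index(a$labels, cloud_truth(30, 3)), 1)
  expect_equal(sum(a$sizes), 90)
  expect_true(all(a$sizes > 0))
  expect_identical(a$labels, cluster_cells(red, 3)$labels)

  singletons <- cluster_cells(cloud_reduced(n_per = 2, k = 3), 6)
  expect_equal(singletons$sizes, rep(1L, 6))
  expect_error(cluster_cells(red, 1), "n must be")
  expect_error(cluster_cells(red, 91), "n must be")
})

test_that("t-SNE layout has the right shape, is seeded, and separates clouds", {
  red <- cloud_reduced(n_per = 20, k = 2, sep = 30)
  co <- tsne_layout(red, seed = 4, perplexity = 8)
  expect_equal(dim(co), c(40, 2))
  expect_identical(co, tsne_layout(red, seed = 4, perplexity = 8))

  truth <- cloud_truth(20, 2)
  d <- as.matrix(dist(co))
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same], na.rm = TRUE), mean(d[same], na.rm = TRUE))

  tiny <- cloud_reduced(n_per = 3, k = 2)
  expect_error(tsne_layout(cloud_reduced(n_per = 1, k = 3)), "too few cells")
  expect_warning(tsne_layout(tiny, perplexity = 30), "perplexity reduced")
})

test_that("mini-batch K-means finds well-separated clouds", {
  red <- cloud_reduced(n_per = 40, k = 3, sep = 30)
  withr::with_seed(8, {
    lab <- minibatch_kmeans(t(red$components), 3, n_iter = 50)
  })
  expect_equal(adjusted_rand_index(lab, cloud_truth(40, 3)), 1)
})
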