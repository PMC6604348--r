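# small in-code fixtures shared across test files

# tiny deterministic counts matrix with obvious structure
tiny_expr <- function() {
  expression_matrix(
    matrix(c(5, 0, 1, 0,
             4, 1, 0, 0,
             0, 0, 6, 5,
             1, 0, 4, 6,
             1, 2, 1, 1), nrow = 5, byrow = TRUE,
           dimnames = list(c("GA1", "GA2", "GB1", "GB2", "HK"),
                           paste0("c", 1:4))))
}

tiny_db <- function() marker_db(list(A = c("GA1", "GA2"), B = c("GB1", "GB2")))

# well-separated Gaussian clouds in low dimension, as a reduced_matrix
cloud_reduced <- function(n_per = 30, k = 3, sep = 20, dims = 5, seed = 42) {
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(k * dims), k, dims) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(stats::rnorm(n_per * dims), n_per, dims), 2,
            centers[i, ], "+")))
  })
  rownames(x) <- sprintf("cell%03d", seq_len(nrow(x)))
  structure(list(components = t(x), explained_variance_fraction = 1,
                 k_pc = dims), class = "reduced_matrix")
}

cloud_truth <- function(n_per = 30, k = 3) rep(seq_len(k), each = n_per)

# brute-force pair-counting ARI oracle (independent of the implementation)
ari_oracle <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (same_a) s10 <- s10 + 1
    else if (same_b) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  tot <- s11 + s10 + s01 + s00
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# brute-force double-loop voting oracle for step (ii)
vote_oracle <- function(M_tilde, Z_support) {
  K <- nrow(M_tilde); C <- ncol(Z_support); M <- ncol(M_tilde)
  V <- matrix(0, K, C, dimnames = list(rownames(M_tilde), colnames(Z_support)))
  for (c in seq_len(C)) {
    denom <- 0
    for (k in seq_len(K)) for (m in seq_len(M))
      denom <- denom + M_tilde[k, m] * Z_support[m, c]
    for (k in seq_len(K)) {
      num <- 0
      for (m in seq_len(M)) num <- num + M_tilde[k, m] * Z_support[m, c]
      V[k, c] <- if (denom > 0) num / denom else 0
    }
  }
  V
}

# random valid binary marker matrix (every row and column nonzero)
random_marker_M <- function(k, m) {
  repeat {
    M <- matrix(stats::rbinom(k * m, 1, 0.4), k, m,
                dimnames = list(paste0("T", seq_len(k)),
                                paste0("G", seq_len(m))))
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
  }
}
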