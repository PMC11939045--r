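# Seeded symmetric fixed-point ICA (tanh contrast).
#
# X: n_signals x n_samples matrix of mixed signals (rows are mixtures).
# Returns unmixed sources S (n_comp x n_samples), the unmixing matrix W in
# whitened space, and the whitening matrix K, so S = W %*% K %*% Xc.
fast_ica_symm <- function(X, n_comp = nrow(X), seed = 1L, maxit = 500,
                          tol = 1e-9) {
  n <- nrow(X); m <- ncol(X)
  stopifnot(n_comp <= n, m > n)
  Xc <- X - rowMeans(X)
  # whitening from the eigen-decomposition of the covariance
  cv <- tcrossprod(Xc) / m
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-30)), n_comp) %*%
    t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / m - diag(rowMeans(Gp), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(S = W %*% Z, W = W, K = K, iterations = it)
}

sym_decorrelate <- function(W) {
  s <- La.svd(W)
  s$u %*% s$vt
}
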