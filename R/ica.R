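# Symmetric fixed-point independent component analysis (tanh contrast)
# with PCA whitening. X: channels x samples. Returns sources S (ncomp x
# samples), mixing matrix A (channels x ncomp, X ~ A S after centering),
# and unmixing W.
fast_ica <- function(X, n_comp = min(nrow(X), 20), max_iter = 500,
                     tol = 1e-6, seed = 1L) {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(min(n_comp, sum(eg$values > 1e-12 * eg$values[1])))
  D <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(D), length(keep)) %*% t(E)     # whitening
  Z <- K %*% Xc
  # estimate the rotation on a subsample; apply to the full data
  Zf <- if (n > 60000) Z[, seq(1, n, by = 2), drop = FALSE] else Z
  nf <- ncol(Zf)
  set.seed(seed)
  W <- matrix(stats::rnorm(length(keep)^2), length(keep))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  best <- list(delta = Inf, W = W)
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Zf)
    W1 <- sym_decorrelate(tcrossprod(G, Zf) / nf -
                            diag(rowMeans(1 - G^2)) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < best$delta) best <- list(delta = delta, W = W)
    if (delta < tol) break
  }
  if (best$delta > 0.1)
    stop("ICA failed to converge")
  W <- best$W
  S <- W %*% Z
  A <- E %*% diag(sqrt(D), length(keep)) %*% t(W)   # channels x comps
  list(S = S, A = A, W = W %*% K, center = mu, n_iter = it,
       delta = best$delta)
}
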