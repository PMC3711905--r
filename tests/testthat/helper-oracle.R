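# Independent oracle for the binary (m = 2) predictive distribution:
# numerical grid quadrature over the posterior of the latent differences
# d_n = f_1(x_n) - f_2(x_n), whose prior is N(0, 2 * scale * (K + jitter I))
# and whose likelihood is prod_n Phi(s_n d_n / sqrt(2)) with s_n = +1 for
# the first class. Entirely independent of the Gibbs sampling path.
binary_probit_oracle <- function(K, labels, k_cross, k_diag, scale = 1,
                                 jitter, npts = 81) {
  n <- nrow(K)
  C2 <- 2 * scale * (K + jitter * diag(n))
  sds <- sqrt(diag(C2))
  grids <- lapply(seq_len(n), function(i) seq(-6, 6, length.out = npts) * sds[i])
  G <- as.matrix(expand.grid(grids))
  Ci <- solve(C2)
  logw <- -0.5 * rowSums((G %*% Ci) * G)
  s <- ifelse(as.integer(labels) == 1L, 1, -1)
  for (i in seq_len(n))
    logw <- logw + pnorm(s[i] * G[, i] / sqrt(2), log.p = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  A <- solve(K + jitter * diag(n))
  a <- k_cross %*% A
  v <- 2 * scale * (k_diag + jitter - rowSums(a * k_cross))
  sapply(seq_len(nrow(k_cross)), function(t)
    sum(w * pnorm((G %*% a[t, ]) / sqrt(2 + v[t]))))
}

# Same machinery for the posterior probability that d_n > 0 at a training
# point (ordering of the two latent functions).
binary_probit_ordering_prob <- function(K, labels, scale = 1, jitter,
                                        npts = 81) {
  n <- nrow(K)
  C2 <- 2 * scale * (K + jitter * diag(n))
  sds <- sqrt(diag(C2))
  grids <- lapply(seq_len(n), function(i) seq(-6, 6, length.out = npts) * sds[i])
  G <- as.matrix(expand.grid(grids))
  Ci <- solve(C2)
  logw <- -0.5 * rowSums((G %*% Ci) * G)
  s <- ifelse(as.integer(labels) == 1L, 1, -1)
  for (i in seq_len(n))
    logw <- logw + pnorm(s[i] * G[, i] / sqrt(2), log.p = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  sapply(seq_len(n), function(i) sum(w[G[, i] > 0]))
}
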