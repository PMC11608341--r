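# Shared fixtures, all generated in code (no stored data).

# random PSD kernel via a Wishart-style crossproduct, mean diagonal ~ 1
make_psd_kernel <- function(n, p = 2 * n, seed = 1, tag = "K") {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  omicreml::omic_kernel(tcrossprod(Z) / p, paste0("S", seq_len(n)), tag = tag)
}

# tiny deterministic SNP panel with optional missingness
make_toy_panel <- function(n = 10, m = 20, seed = 1, missing_rate = 0) {
  omicreml::simulate_genotypes(n, m, maf_range = c(0.1, 0.5),
                               missing_rate = missing_rate, seed = seed)
}

# literal double-loop GRM oracle (per-element formula, mean-imputation)
grm_oracle <- function(panel) {
  X <- panel$dosages
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  poly <- which(p_hat > 0 & p_hat < 1)
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in poly) {
      xi <- X[i, k]; xj <- X[j, k]
      if (is.na(xi)) xi <- 2 * p_hat[k]
      if (is.na(xj)) xj <- 2 * p_hat[k]
      s <- s + (xi - 2 * p_hat[k]) * (xj - 2 * p_hat[k]) /
        (2 * p_hat[k] * (1 - p_hat[k]))
    }
    A[i, j] <- s / length(poly)
  }
  A
}

# dense independent evaluation of the restricted log-likelihood
reml_loglik_oracle <- function(theta, y, X, mats) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(mats)) V <- V + theta[i] * mats[[i]]
  Vinv <- solve(V)
  XtVX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtVX) %*% t(X) %*% Vinv
  -0.5 * (determinant(V)$modulus[1] + determinant(XtVX)$modulus[1] +
            drop(t(y) %*% P %*% y))
}
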