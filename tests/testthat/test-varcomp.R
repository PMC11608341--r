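# The AI-REML engine: closed-form and dense-oracle checks, optimality
# properties, LRT, proportions, power.

test_that("residual-only model matches the closed-form REML solution", {
  set.seed(15)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  fit <- reml_fit(y, X, variance_model(list()))
  p <- ncol(X)
  rss <- sum(qr.resid(qr(X), y)^2)
  s2 <- rss / (n - p)
  expect_equal(unname(fit$theta[["residual"]]), s2, tolerance = 1e-7)
  logL_closed <- -0.5 * ((n - p) * (log(s2) + 1) +
                           determinant(crossprod(X))$modulus[1])
  expect_equal(fit$logL, logL_closed, tolerance = 1e-7)
})

test_that("converged logL matches an independent dense evaluation", {
  set.seed(16)
  n <- 12
  K <- make_psd_kernel(n, seed = 16)
  X <- cbind(1, rnorm(n))
  # strong signal so the optimum is interior (gradient must vanish there)
  y <- 0.5 * rnorm(n) + 1.5 * drop(kernel_sqrt(K) %*% rnorm(n))
  fit <- reml_fit(y, X, variance_model(list(G = K)))
  oracle <- reml_loglik_oracle(unname(fit$theta), y, X, list(K$values))
  expect_equal(fit$logL, oracle, tolerance = 1e-8)
  expect_lt(max(abs(fit$grad)), 1e-5)
})

test_that("fitted optimum beats 200 random parameter points", {
  set.seed(17)
  n <- 30
  K <- make_psd_kernel(n, seed = 17)
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) * 0.8 + rnorm(n) * 0.6
  X <- matrix(1, n, 1)
  fit <- reml_fit(y, X, variance_model(list(G = K)))
  vp <- var(y)
  for (i in 1:200) {
    th <- runif(2, 0.01, 2) * vp
    ll <- reml_loglik_oracle(th, y, X, list(K$values))
    expect_lte(ll, fit$logL + 1e-8)
  }
  expect_lt(max(abs(fit$grad)), 1e-5)
})

test_that("EM and AI updates share the fitted fixed point", {
  set.seed(18)
  n <- 60
  K <- make_psd_kernel(n, seed = 18)
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) + rnorm(n)
  fit <- reml_fit(y, model = variance_model(list(G = K)))
  th <- unname(fit$theta)
  # dense EM update at the optimum
  V <- th[1] * K$values + th[2] * diag(n)
  Vinv <- solve(V)
  X <- matrix(1, n, 1)
  P <- Vinv - Vinv %*% X %*% solve(t(X) %*% Vinv %*% X) %*% t(X) %*% Vinv
  Py <- drop(P %*% y)
  em <- c(th[1] + th[1]^2 / n * (sum(Py * (K$values %*% Py)) -
                                   sum(P * K$values)),
          th[2] + th[2]^2 / n * (sum(Py^2) - sum(diag(P))))
  expect_lt(max(abs(em - th) / pmax(abs(th), 1e-8)), 1e-6)
})

test_that("estimates are permutation-equivariant", {
  set.seed(19)
  n <- 50
  K <- make_psd_kernel(n, seed = 19)
  X <- cbind(1, rnorm(n))
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) + rnorm(n)
  fit1 <- reml_fit(y, X, variance_model(list(G = K)))
  perm <- sample(n)
  Kp <- kernel_subset(K, perm)
  fit2 <- reml_fit(y[perm], X[perm, , drop = FALSE],
                   variance_model(list(G = Kp)))
  expect_equal(fit1$theta, fit2$theta, tolerance = 1e-8)
  expect_equal(fit1$logL, fit2$logL, tolerance = 1e-8)
})

test_that("identical kernels in a covariance pair are flagged, not silently fit", {
  set.seed(20)
  n <- 40
  K <- make_psd_kernel(n, seed = 20)
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) + rnorm(n)
  terms <- list(A = K, B = K)
  m <- variance_model(terms, list(cov_pair("rA.B", "A", "B",
                                           terms = terms)))
  fit <- suppressWarnings(core_reml_fit(y, model = m,
                                        opts = reml_opts(max_iter = 40)))
  expect_true(!fit$converged || any(fit$constrained) ||
                any(!is.finite(fit$se)))
})

test_that("core_reml_fit demands a covariance pair", {
  K <- make_psd_kernel(20, seed = 21)
  expect_error(core_reml_fit(rnorm(20), model = variance_model(list(G = K))),
               "covariance pair")
})

test_that("lrt computes plain and boundary-mixture p-values", {
  mk_fit <- function(logL, pars) {
    structure(list(logL = logL, theta = setNames(rep(1, length(pars)),
                                                 pars),
                   par_names = pars, n = 100), class = "reml_fit")
  }
  f0 <- mk_fit(-100, c("residual"))
  f1 <- mk_fit(-100, c("G", "residual"))
  expect_equal(as.numeric(lrt(f1, f0)), 1)                 # Lambda = 0
  expect_equal(as.numeric(lrt(f1, f0, boundary = TRUE)), 1)

  f2 <- mk_fit(-100 + 3.84 / 2, c("G", "residual"))
  expect_equal(as.numeric(lrt(f2, f0)), 0.05, tolerance = 1e-3)

  # 2.71 is the 90% point of chisq_1, so the mixture gives 0.10 / 2
  f3 <- mk_fit(-100 + 2.71 / 2, c("G", "residual"))
  expect_equal(as.numeric(lrt(f3, f0, boundary = TRUE)), 0.05,
               tolerance = 3e-3)

  # logL inversion beyond tolerance is an error
  f4 <- mk_fit(-101, c("G", "residual"))
  expect_error(lrt(f4, f0), "below reduced")
  # non-nested models rejected
  f5 <- mk_fit(-99, c("E", "residual"))
  expect_error(lrt(f1, f5), "not nested")
})

test_that("variance proportions sum to one and track the delta method", {
  set.seed(22)
  n <- 80
  K <- make_psd_kernel(n, seed = 22)
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) + rnorm(n)
  fit <- reml_fit(y, model = variance_model(list(G = K)))
  pr <- fit$proportions
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-10)

  # delta-method SE equals a finite-difference propagation of the ratio
  iv <- which(fit$is_var)
  Sg <- fit$cov_theta[iv, iv]
  for (r in seq_along(iv)) {
    h <- function(th) th[r] / sum(th)
    th0 <- fit$theta[iv]
    g <- numeric(length(iv))
    eps <- 1e-7
    for (j in seq_along(iv)) {
      up <- th0; up[j] <- up[j] + eps
      dn <- th0; dn[j] <- dn[j] - eps
      g[j] <- (h(up) - h(dn)) / (2 * eps)
    }
    expect_equal(pr$se[r], sqrt(drop(t(g) %*% Sg %*% g)),
                 tolerance = 1e-6)
  }
})

test_that("greml_power implements the closed form", {
  pw <- greml_power(10000, 0.025)
  expect_equal(pw$se_h2, sqrt(2 / (1e8 * 2e-5)), tolerance = 1e-12)
  expect_equal(pw$se_h2, sqrt(1e-3), tolerance = 1e-12)

  # null limit: power -> alpha as h2 -> 0
  expect_equal(greml_power(10000, 1e-9)$power, 0.05, tolerance = 1e-6)

  # scaling law: doubling n halves se
  expect_equal(greml_power(20000, 0.025)$se_h2, pw$se_h2 / 2,
               tolerance = 1e-12)

  expect_error(greml_power(10000, 0.025, var_offdiag = 0), "positive")
  expect_error(greml_power(10000, 1.5), "h2")
})

test_that("non-convergence is reported, never silent", {
  set.seed(23)
  n <- 30
  K <- make_psd_kernel(n, seed = 23)
  y <- drop(kernel_sqrt(K) %*% rnorm(n)) + rnorm(n)
  expect_warning(fit <- reml_fit(y, model = variance_model(list(G = K)),
                                 opts = reml_opts(max_iter = 2)),
                 "converge")
  expect_false(fit$converged)
})

test_that("variance floor clamps a null component and flags it", {
  set.seed(24)
  n <- 150
  K <- make_psd_kernel(n, seed = 24)
  y <- rnorm(n)                     # no genetic signal at all
  fit <- reml_fit(y, model = variance_model(list(G = K)))
  if (any(fit$constrained)) {
    expect_equal(unname(fit$theta[["G"]]), fit$var_floor, tolerance = 1e-12)
  } else {
    expect_lt(fit$proportions$proportion[1], 0.2)
  }
})
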