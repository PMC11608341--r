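# BLUP risk scores, cross-validated scoring, linear mediation with
# bootstrap CIs.

test_that("blup_risk_score contracts: null component, leakage", {
  set.seed(25)
  n <- 80
  tr <- sim_truth(c(G = 0.5, residual = 0.5), seed = 25)
  sim <- simulate_multiomics(n, tr, layer_sizes = c(G = 100))
  test_idx <- 1:20; train_idx <- 21:n
  Kfull <- sim$kernels$G
  Ktr <- kernel_subset(Kfull, train_idx)
  fit <- reml_fit(sim$liability[train_idx],
                  model = variance_model(list(G = Ktr)))
  Kc <- Kfull$values[test_idx, train_idx]

  # forcing the component to zero zeroes the scores
  fit0 <- fit
  fit0$theta[["G"]] <- 0
  sc0 <- blup_risk_score(fit0, list(G = Kc))
  expect_true(all(sc0 == 0))

  # leakage: a test row that is a training sample
  Kleak <- Kfull$values[train_idx[1:5], train_idx]
  expect_error(blup_risk_score(fit, list(G = Kleak)), "leakage")

  # honest scores correlate positively with the realized effects
  sc <- blup_risk_score(fit, list(G = Kc))
  expect_gt(cor(sc[, "G"], sim$effects$G[test_idx]), 0)
})

test_that("BLUP prediction accuracy matches simulation over seeds", {
  # scaled down from the stated n_train=1600/n_test=400 x 20 seeds to keep
  # the suite fast; the check is still against the realized effects
  seeds <- 1:8
  cors <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    tr <- sim_truth(c(G = 0.5, residual = 0.5), seed = 300 + seeds[i])
    sim <- simulate_multiomics(400, tr, layer_sizes = c(G = 400))
    test_idx <- 1:80; train_idx <- 81:400
    Ktr <- kernel_subset(sim$kernels$G, train_idx)
    fit <- reml_fit(sim$liability[train_idx],
                    model = variance_model(list(G = Ktr)))
    Kc <- sim$kernels$G$values[test_idx, train_idx]
    sc <- blup_risk_score(fit, list(G = Kc))
    cors[i] <- cor(sc[, "G"], sim$effects$G[test_idx])
  }
  mc_se <- sd(cors) / sqrt(length(seeds))
  expect_gt(mean(cors), 0)
  expect_gt(mean(cors) - 2 * mc_se, 0)
})

test_that("cv folds are balanced, disjoint, exhaustive, deterministic", {
  f <- make_cv_folds(100, 5, seed = 26)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  expect_identical(f, make_cv_folds(100, 5, seed = 26))
  expect_false(identical(f, make_cv_folds(100, 5, seed = 27)))

  # stratified: each status level spread across folds
  status <- rep(c(0, 0, 0, 1), 25)
  fs <- make_cv_folds(100, 5, status = status, seed = 26)
  expect_equal(unname(table(fs)), rep(20L, 5), ignore_attr = TRUE)
  tab <- table(fs, status)
  expect_true(all(tab[, "1"] == 5))
})

test_that("cv_risk_scores scores every sample exactly once per layer", {
  tr <- sim_truth(c(G = 0.4, E = 0.2, residual = 0.4), seed = 28)
  sim <- simulate_multiomics(120, tr, layer_sizes = c(G = 80, E = 10))
  rs <- cv_risk_scores(sim$liability, sim$kernels[c("G", "E")],
                       status = sim$status, k = 4, seed = 28)
  expect_false(anyNA(rs$scores$G))
  expect_false(anyNA(rs$scores$E))
  expect_setequal(rs$scores$sample_id, sim$sample_ids)
  expect_equal(sort(unique(rs$scores$fold)), 1:4)
  expect_error(cv_risk_scores(sim$liability, sim$kernels["G"], k = 1),
               "k must be")
  expect_error(cv_risk_scores(rnorm(30), sim$kernels["G"], k = 5),
               "n >= 10")
})

test_that("mediate_linear recovers a linear mediation truth", {
  set.seed(29)
  n <- 4000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.3 * x + 0.4 * m + rnorm(n)
  med <- mediate_linear(x, m, y, n_boot = 300, seed = 29)
  expect_lt(abs(med$acme - 0.2), 0.05)
  expect_lt(abs(med$total - 0.5), 0.06)
  expect_lt(abs(med$prop_mediated - 0.4), 0.1)
  expect_lte(med$ci["lower", "acme"], med$acme)
  expect_gte(med$ci["upper", "acme"], med$acme)

  # algebraic identities on any fitted instance
  expect_equal(med$total, med$de + med$acme, tolerance = 1e-10)
  # difference-of-coefficients estimator equals a*b
  total_coef <- cov(x, y) / var(x)
  expect_equal(med$acme, total_coef - med$c_prime, tolerance = 1e-10)
})

test_that("mediate_linear handles the null mediator and bad input", {
  set.seed(30)
  n <- 500
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.3 * x + rnorm(n)        # y independent of m given x
  med <- mediate_linear(x, m, y, n_boot = 300, seed = 30)
  expect_lte(med$ci["lower", "acme"], 0)
  expect_gte(med$ci["upper", "acme"], 0)

  expect_error(mediate_linear(rep(1, 100), rnorm(100), rnorm(100)),
               "zero-variance")
  expect_error(mediate_linear(rnorm(10), rnorm(10), rnorm(10)),
               "n >= 30")
})

test_that("bootstrap is deterministic under the seed", {
  set.seed(31)
  x <- rnorm(200); m <- 0.5 * x + rnorm(200); y <- 0.4 * m + rnorm(200)
  m1 <- mediate_linear(x, m, y, n_boot = 100, seed = 7)
  m2 <- mediate_linear(x, m, y, n_boot = 100, seed = 7)
  expect_identical(m1$ci, m2$ci)
})

test_that("summarize_cv_mediation reproduces the arithmetic", {
  mk <- function(p) structure(list(prop_mediated = p, acme = p, total = 1,
                                   ci = matrix(c(p - 0.1, p + 0.1), 2, 7,
                                               dimnames = list(c("lower", "upper"),
                                                               c("a", "b", "c_prime", "acme", "de",
                                                                 "total", "prop_mediated")))),
                              class = "mediation_fit")
  props <- c(0.46, 0.60, 0.83, 0.55, 0.56)
  s <- summarize_cv_mediation(lapply(props, mk))
  expect_equal(s$mean_prop, 0.6)
  expect_equal(s$range_prop, c(0.46, 0.83))

  # permutation-invariant mean; identical fits collapse the range
  s2 <- summarize_cv_mediation(lapply(rev(props), mk))
  expect_equal(s2$mean_prop, s$mean_prop)
  s3 <- summarize_cv_mediation(lapply(c(0.5, 0.5), mk))
  expect_equal(s3$range_prop, c(0.5, 0.5))

  expect_error(summarize_cv_mediation(list(mk(0.5))), ">= 2")
})
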