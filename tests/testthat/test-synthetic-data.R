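# Synthetic multi-omics generator: genotypes, liability thresholds, effect
# bookkeeping, determinism.

test_that("simulate_genotypes respects the frequency model", {
  # at p = 0.5 the dosage distribution is symmetric around 1
  g <- simulate_genotypes(4000, 3, maf_range = c(0.5, 0.5), seed = 1)
  expect_true(all(abs(colMeans(g$dosages) - 1) < 0.06))

  # per-SNP sample frequencies track the drawn p within binomial bounds
  g <- simulate_genotypes(2000, 500, maf_range = c(0.05, 0.5), seed = 7)
  p <- g$snp_meta$freq
  phat <- colMeans(g$dosages) / 2
  bound <- 3 * sqrt(p * (1 - p) / (2 * 2000))
  expect_gte(mean(abs(phat - p) <= bound), 0.99)
})

test_that("simulate_genotypes missingness and validation", {
  g <- simulate_genotypes(500, 200, missing_rate = 0.5, seed = 2)
  expect_lt(abs(mean(is.na(g$dosages)) - 0.5), 0.02)

  expect_error(simulate_genotypes(100, 10, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotypes(100, 10, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(simulate_genotypes(1, 10), "n_samples")
  expect_error(simulate_genotypes(10, 10, missing_rate = 1), "missing_rate")
})

test_that("generator is deterministic and seed-splittable", {
  g1 <- simulate_genotypes(50, 30, seed = 11)
  g2 <- simulate_genotypes(50, 30, seed = 11)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- simulate_genotypes(50, 30, seed = 12)
  expect_false(identical(g1$dosages, g3$dosages))

  tr <- sim_truth(c(G = 0.4, E = 0.2, residual = 0.4), seed = 9)
  s1 <- simulate_multiomics(100, tr, layer_sizes = c(G = 50, E = 10))
  s2 <- simulate_multiomics(100, tr, layer_sizes = c(G = 50, E = 10))
  expect_identical(s1$liability, s2$liability)
  expect_identical(s1$status, s2$status)
})

test_that("liability_to_ordinal applies quantile cut-points", {
  lia <- c(3, 2, 1, 0, -1, -2, -3, -4, -5, -6)
  code <- liability_to_ordinal(lia, case_fraction = 0.2,
                               severe_fraction_of_cases = 0.5)
  expect_identical(code, c(2L, 1L, rep(0L, 8)))

  set.seed(1)
  lia <- rnorm(10000)
  code <- liability_to_ordinal(lia, case_fraction = 0.095)
  expect_equal(sum(code >= 1), 950)

  code0 <- liability_to_ordinal(lia, case_fraction = 0.2,
                                severe_fraction_of_cases = 0)
  expect_equal(sum(code0 == 2), 0)

  expect_error(liability_to_ordinal(rep(1, 10), 0.2), "constant")
  expect_error(liability_to_ordinal(lia, 0), "case_fraction")
})

test_that("ordinal coding preserves liability ranks", {
  for (s in 1:5) {
    set.seed(s)
    lia <- rnorm(200)
    code <- liability_to_ordinal(lia, case_fraction = 0.1,
                                 severe_fraction_of_cases = 0.4)
    o <- order(lia)
    expect_true(all(diff(code[o]) >= -1e-9 | diff(sort(code)) >= 0))
    # codes sorted by liability must be non-decreasing
    expect_true(all(diff(code[o]) >= 0))
  }
})

test_that("sim_truth validates its invariants", {
  expect_error(sim_truth(c(G = 0.5, residual = 0.4)), "sum to 1")
  expect_error(sim_truth(c(G = -0.1, residual = 1.1)), ">= 0")
  expect_error(sim_truth(c(G = 0.5, residual = 0.5), c(rX.Y = 0.1)),
               "unknown covariance")
  expect_error(sim_truth(c(G = 0.1, E = 0.1, residual = 0.8),
                         c(rG.E = 0.2)), "violates")
  expect_error(sim_truth(c(G = 1)), "residual")
  # one layer in two pairs is rejected
  expect_error(sim_truth(c(G = 0.2, T = 0.2, E = 0.2, residual = 0.4),
                         c(rG.E = 0.1, rT.E = 0.1)), "at most one")
})

test_that("null model gives an iid standard-normal liability", {
  tr <- sim_truth(c(residual = 1.0), seed = 21)
  sim <- simulate_multiomics(5000, tr, layer_sizes = c(G = 10))
  expect_null(sim$geno)
  expect_lt(abs(var(sim$liability) - 1), 0.05)
  expect_lt(abs(mean(sim$liability)), 0.05)
})

test_that("additive variance bookkeeping holds across replicates", {
  # across-replicate variance of the realized genetic effect converges to
  # sigma2 * mean(diag K); scaled down (n = 400, m = 300, 50 reps) to stay
  # inside the suite's runtime budget
  n <- 400; reps <- 50
  ratios <- numeric(reps)
  for (s in seq_len(reps)) {
    tr <- sim_truth(c(G = 0.5, residual = 0.5), seed = 1000 + s)
    sim <- simulate_multiomics(n, tr, layer_sizes = c(G = 300))
    ratios[s] <- mean(sim$effects$G^2) / mean(diag(sim$kernels$G$values))
  }
  mc_se <- sd(ratios) / sqrt(reps)
  expect_lt(abs(mean(ratios) - 0.5), 3 * mc_se)
})

test_that("covariance bookkeeping matches the CORE-GREML structure", {
  # E[mean_i(g_A,i * g_B,i)] = sigma12 * mean(diag(S_A S_B)) per replicate
  n <- 60; reps <- 150
  diffs <- numeric(reps)
  for (s in seq_len(reps)) {
    tr <- sim_truth(c(G = 0.3, E = 0.3, residual = 0.4), c(rG.E = 0.15),
                    seed = 2000 + s)
    sim <- simulate_multiomics(n, tr, layer_sizes = c(G = 120, E = 20))
    SG <- kernel_sqrt(sim$kernels$G)
    SE <- kernel_sqrt(sim$kernels$E)
    expected <- 0.15 * mean(diag(SG %*% SE))
    diffs[s] <- mean(sim$effects$G * sim$effects$E) - expected
  }
  mc_se <- sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("simulate_multiomics rejects invalid covariance requests", {
  expect_error(
    simulate_multiomics(50, sim_truth(c(G = 0.5, residual = 0.5),
                                      seed = 1),
                        layer_sizes = c(G = 20, E = 5)),
    NA) # baseline: valid truth simulates fine
  tr <- sim_truth(c(G = 0.3, E = 0.3, residual = 0.4), c(rG.E = 0.29),
                  seed = 1)
  expect_s3_class(simulate_multiomics(50, tr,
                                      layer_sizes = c(G = 20, E = 5)),
                  "multiomics_sim")
})

test_that("case fraction flows through to the ordinal status", {
  tr <- sim_truth(c(G = 0.3, residual = 0.7), case_fraction = 0.095,
                  severe_fraction = 0.5, seed = 31)
  sim <- simulate_multiomics(2000, tr, layer_sizes = c(G = 100))
  expect_equal(sum(sim$status >= 1), round(0.095 * 2000))
  expect_equal(sum(sim$status == 2), round(0.5 * round(0.095 * 2000)))
})
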