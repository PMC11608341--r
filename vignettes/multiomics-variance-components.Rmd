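---
title: "Partitioning an ordinal disease phenotype across multi-omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning an ordinal disease phenotype across multi-omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

How much of the person-to-person variation in an ordinal disease outcome
(0 = negative, 1 = moderate case, 2 = severe case) is attributable to common
genetic variants, to imputed tissue gene expression, to circulating
metabolites, and to measured environmental and lifestyle factors (the
exposome)? And how much of the genetic or metabolomic signal is *mediated*
by the exposome? `omicreml` implements the full analysis chain for these
questions on individual-level data: kernel construction, variance-component
estimation, model comparison, power, and risk-score mediation — plus a
synthetic generator with known ground truth so every stage is testable
without access-restricted cohort data.

## The model

Each omics layer contributes a random effect through an n x n
sample-similarity kernel. For the genome this is the GRM with entries

    A_ij = (1/m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k)),

the GCTA estimator over m polymorphic SNPs with missing dosages
mean-imputed to 2 p_k. Transcriptomic, metabolomic and exposomic
relationship matrices (TRM/MRM/ERM) are average cross-products
K = Z Z' / p of column-standardized feature matrices. The phenotype model is

    y = X b + sum_i g_i + e,     g_i ~ N(0, sigma2_i K_i),
    V = sum_i sigma2_i K_i + sum_p sigma12_p C_p + sigma2_e I.

Three kinds of components appear in V:

* **additive** terms, one per layer kernel;
* **interaction** terms, whose kernels are Hadamard (elementwise) products
  K1 * K2 — PSD by the Schur product theorem — modelling multiplicative
  interplay such as gene-environment interaction;
* **covariance** terms (the CORE-GREML extension): the coefficient matrix
  of the covariance sigma12 between two random effects is
  C = (S1 S2' + S2 S1')/2, where S_i is the *symmetric* square root of
  K_i. Symmetric (rather than Cholesky) roots make C basis-independent and
  symmetric without an extra symmetrization error.

Parameters are estimated by restricted maximum likelihood: one EM warm-up
iteration for stability, then average-information (AI) Newton steps with
step-halving. Per iteration only one Cholesky factorization of V is
required; traces tr(P K) are elementwise sums and the AI matrix needs only
matrix-vector products, so the per-iteration cost is O(n^3) + O(q n^2) for
q parameters. This keeps the engine practical to n of order 10^4 on a
single desktop core; cohort-scale n > 10^5 is out of scope by design.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.01 | SNPs with minor allele frequency below 1% removed |
| `hwe_alpha` | 1e-7 | Hardy-Weinberg chi-square p-value threshold |
| `call_rate_min` | 0.95 | minimum per-SNP call rate |
| `info_min` | 0.60 | minimum imputation info score (metadata pass-through) |
| `miss_max` | 0.05 | maximum per-sample genotype missing rate |
| relatedness `cutoff` | 0.05 | greedy GRM pruning threshold |
| `tol` | 1e-8 | REML convergence: change in restricted logL (plus max relative parameter change < 1e-6) |
| `var_floor_frac` | 1e-6 | variance floor as a fraction of phenotypic variance |
| `var_offdiag` | 2e-5 | variance of off-diagonal kernel entries in the power formula (typical for unrelated genotyped samples) |
| `case_fraction` | 0.095 | simulated case rate (the positive-test rate the generator emulates) |
| `n_boot` | 1000 | mediation bootstrap replicates |

## Estimation details and numerical choices

* **Initialization.** All variance parameters start at Vp/(k+1) (equal
  split including the residual); covariances start at 0. Overridable via
  `reml_opts(theta_init = ...)`.
* **Constraints.** Variances are clamped at `var_floor_frac * Vp` and
  flagged (GCTA-style), rather than handled by a full constrained
  optimizer; parameters held at the floor with an outward-pointing gradient
  are dropped from the AI update (active set), so the free-parameter
  gradient vanishes at convergence (KKT). Covariances are projected at each
  step so each pair's 2x2 component matrix stays PSD
  (|sigma12| <= sqrt(sigma2_1 sigma2_2)), and flagged when the projection
  is active.
* **Standard errors** come from the inverse AI matrix at convergence;
  variance *proportions* sigma2_i / sigma2_P and effect *correlations*
  sigma12 / sqrt(sigma2_1 sigma2_2) get first-order delta-method SEs using
  the full parameter covariance. When the AI matrix is singular (e.g. two
  identical kernels joined by a covariance term — an unidentifiable model)
  SEs are reported as NA and the fit is marked non-converged, never
  silently finite.
* **Likelihood-ratio tests.** For a single variance component on the
  boundary of its parameter space the null distribution is the 50:50
  mixture of chi-square(0) and chi-square(1). Because a truly null
  component is clamped at a small *positive* floor, the full model's logL
  can sit marginally below the reduced model's; the inversion tolerance is
  therefore relative to |logL| and such cases give Lambda = 0, p = 1
  (conservative).
* **Fixed-effect adjustment.** The ordinal 0/1/2 code is pre-adjusted by
  OLS on dummy-coded factors (batch, assessment centre). The downstream
  mixed model treats the phenotype as Gaussian, so a least-squares
  adjustment is the consistent choice; an ordinal-logit link is a known
  alternative and deliberately out of scope. Residual standardization
  defaults on, so components read as fractions of adjusted phenotypic
  variance.
* **Kernel scaling.** How interaction matrices were scaled in the source
  analyses is not stated; `omicreml` trace-normalizes every kernel to mean
  diagonal 1 by default so each sigma2 is interpretable as a variance
  fraction. A flag disables it.
* **Relatedness pruning** is specified only as "> 5%" in the emulated
  pipeline; the implementation is greedy max-degree removal (ties broken by
  input order), mimicking `gcta --grm-cutoff`, and is fully deterministic.
* **Power.** se(h2) = sqrt(2 / (n^2 var_offdiag)); the non-centrality is
  (h2/se)^2 and power is the upper tail of the non-central chi-square(1)
  at the alpha critical value — the standard GREML power calculation.

## Risk scores and mediation

Per-layer risk scores are BLUPs of the random effects for held-out
samples: g_test = sigma2_term K_cross V_train^-1 (y - X beta_hat). Scores
are produced either from a single 80/20 split or — the default for
headline numbers — by seeded, status-stratified 5-fold cross-validation,
so no sample is ever scored by a model trained on itself.

Mediation is specialized to the linear-linear case, which is exactly the
estimand for continuous risk scores and a continuous adjusted outcome: with
mediator model m = a0 + a x and outcome model y = b0 + c' x + b m, the
average causal mediation effect is ACME = a*b, the direct effect is c',
the total effect is c' + a*b (an exact decomposition), and the proportion
mediated is ACME/total. All quantities carry seeded percentile-bootstrap
confidence intervals. When |total| < 1e-3 sd(y) the proportion is reported
raw with an instability flag rather than silently truncated. Mediation
regressions are score-only by default; a covariate hook exists but the
emulated analysis did not state any additional covariates.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the emulated cohort study:
biallelic dosages with a uniform allele-frequency spectrum; layer feature
matrices (defaults 1634 expression features, 249 metabolites, 43 exposome
features) optionally driven in part by SNP subsets; per-layer variance
contributions that can be set to the 0.5-4% range reported for real data;
interaction effects drawn through Hadamard-kernel square roots; covariances
induced by shared latent normals so cov(g1, g2) matches the CORE-GREML
structure; and a liability-threshold ordinal phenotype with a 9.5% case
rate, split 50/50 into moderate and severe by quantile cut-points (whether
the real severity levels are equidistant on the liability scale is unknown;
quantile thresholds are an explicit modelling choice here). All randomness
flows from a single master seed through fixed sub-streams, so any component
can be regenerated independently and runs are bit-reproducible.

It does **not** emulate: linkage disequilibrium, MAF-dependent effect
sizes, non-integer imputed dosages, eQTL-based expression imputation
(feature matrices stand in for imputed expression directly), or
cohort-scale sample sizes. A green recovery test therefore establishes that
the estimator is unbiased and calibrated *under this stated world* — not
that the reported cohort estimates are themselves correct. One structural
restriction: each layer may enter at most one covariance pair per simulated
dataset, matching the fitted model families, which never use more.

## Known limitations

* Dense linear algebra bounds practical n at roughly 10^4 per fit.
* The ordinal outcome is analysed as Gaussian after adjustment; threshold
  models on the liability scale are not implemented.
* The greedy relatedness pruning is one reasonable determinization of an
  under-specified step; other rules can retain different sample sets.
* Sample alignment across files is by id intersection, never row order;
  dropped counts are logged but not reconciled automatically.
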