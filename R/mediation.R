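# Omics risk scores (BLUP) with cross-validation, and linear mediation
# analysis (ACME, direct effect, total effect, proportion mediated) with
# percentile bootstrap confidence intervals.

#' BLUP risk scores for held-out samples
#'
#' Best linear unbiased prediction of each random-effect term for test
#' samples, from a REML fit on training samples:
#' g_test = sigma2_term * K_cross %*% V_train^-1 (y_train - X_train beta_hat)
#' where K_cross is the test x train block of the term's full kernel.
#'
#' @param fit a converged `reml_fit` on the training samples
#' @param K_cross named list (by term) of test x train kernel blocks with
#'   dimnames carrying sample ids; a single matrix is accepted for a
#'   one-term model
#' @param y_train training phenotype (defaults to the one stored in `fit`)
#' @param terms which terms to score (default: all)
#' @return matrix of scores, n_test x length(terms)
#' @export
blup_risk_score <- function(fit, K_cross, y_train = fit$y,
                            terms = names(fit$model$terms)) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged)
    warning("scoring from a non-converged fit")
  if (is.matrix(K_cross)) {
    if (length(fit$model$terms) != 1)
      stop_omicreml("a bare matrix K_cross needs a single-term model")
    K_cross <- stats::setNames(list(K_cross), names(fit$model$terms))
  }
  train_ids <- fit$model$terms[[1]]$sample_ids
  n <- fit$n
  if (length(y_train) != n) stop_omicreml("y_train length != training n")
  # rebuild V on the training block and the GLS residual
  npar <- length(fit$theta)
  V <- diag(fit$theta[npar], n)
  k <- length(fit$model$terms)
  for (i in seq_len(k)) V <- V + fit$theta[i] * fit$model$terms[[i]]$values
  for (p in seq_along(fit$model$cov_pairs))
    V <- V + fit$theta[k + p] * fit$model$cov_pairs[[p]]$C$values
  ch <- chol(V)
  Vinv_y <- backsolve(ch, backsolve(ch, fit$y, transpose = TRUE))
  Vinv_X <- backsolve(ch, backsolve(ch, fit$X, transpose = TRUE))
  beta <- solve(crossprod(fit$X, Vinv_X), crossprod(fit$X, Vinv_y))
  r <- y_train - drop(fit$X %*% beta)
  u <- backsolve(ch, backsolve(ch, r, transpose = TRUE))

  out <- NULL
  for (tm in terms) {
    Kc <- K_cross[[tm]]
    if (is.null(Kc)) stop_omicreml("no K_cross block for term '", tm, "'")
    if (ncol(Kc) != n)
      stop_omicreml("K_cross for '", tm, "' has ", ncol(Kc),
                    " columns; training n is ", n)
    if (!is.null(colnames(Kc)) && !identical(colnames(Kc), train_ids))
      stop_omicreml("K_cross columns for '", tm,
                    "' do not match training sample ids")
    if (!is.null(rownames(Kc))) {
      leak <- intersect(rownames(Kc), train_ids)
      if (length(leak))
        stop_omicreml("id leakage: test sample(s) present in training set: ",
                      paste(utils::head(leak, 3), collapse = ", "))
    }
    s2 <- fit$theta[tm]
    sc <- if (s2 == 0) rep(0, nrow(Kc)) else s2 * drop(Kc %*% u)
    out <- cbind(out, sc)
  }
  colnames(out) <- terms
  rownames(out) <- rownames(K_cross[[terms[1]]])
  out
}

#' Cross-validated risk scores for every sample
#'
#' Partitions samples into k seeded folds (stratified by ordinal status when
#' given), fits the joint variance model on each fold's complement and
#' scores the held-out fold, so every sample is scored exactly once per
#' layer and never by a model trained on itself.
#'
#' @param y adjusted phenotype
#' @param kernels named list of `omic_kernel`s (one per layer/term)
#' @param X fixed-effect design (default intercept)
#' @param status optional ordinal status for stratified folds
#' @param k number of folds (default 5)
#' @param seed integer seed for the fold assignment
#' @param opts REML options passed to [reml_fit()]
#' @return object of class `risk_scores`: data.frame `scores` (sample_id,
#'   fold, one column per term) plus the per-fold fits
#' @export
cv_risk_scores <- function(y, kernels, X = NULL, status = NULL, k = 5L,
                           seed = 1L, opts = reml_opts()) {
  n <- length(y)
  if (k < 2) stop_omicreml("k must be >= 2")
  if (n < 10 * k) stop_omicreml("need n >= 10*k samples for ", k, " folds")
  for (kk in kernels) stopifnot(inherits(kk, "omic_kernel"))
  ids <- kernels[[1]]$sample_ids
  if (is.null(X)) X <- matrix(1, n, 1)

  fold <- make_cv_folds(n, k, status = status, seed = seed)

  score_mat <- matrix(NA_real_, n, length(kernels),
                      dimnames = list(ids, names(kernels)))
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    if (stats::sd(y[train]) == 0)
      stop_omicreml("fold ", f, " leaves a constant training phenotype")
    sub_kerns <- lapply(kernels, kernel_subset, samples = train)
    fit <- reml_fit(y[train], X[train, , drop = FALSE],
                    variance_model(sub_kerns), opts = opts)
    Kc <- lapply(kernels, function(kk)
      kk$values[test, train, drop = FALSE])
    score_mat[test, ] <- blup_risk_score(fit, Kc, y_train = y[train])
    fits[[f]] <- fit
  }
  structure(list(scores = data.frame(sample_id = ids, fold = fold,
                                     score_mat, stringsAsFactors = FALSE),
                 fits = fits, k = k, seed = seed),
            class = "risk_scores")
}

#' Seeded (optionally stratified) fold assignment
#'
#' @param n number of samples
#' @param k number of folds
#' @param status optional stratification variable
#' @param seed integer seed
#' @return integer vector of fold labels 1..k
#' @export
make_cv_folds <- function(n, k, status = NULL, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 51L))
  fold <- integer(n)
  strata <- if (is.null(status)) list(seq_len(n)) else
    split(seq_len(n), status)
  offset <- 0L
  for (s in strata) {
    perm <- s[sample.int(length(s))]
    # deal round-robin, continuing the deal across strata so totals balance
    fold[perm] <- ((seq_along(perm) + offset - 1L) %% k) + 1L
    offset <- (offset + length(perm)) %% k
  }
  fold
}

#' Linear mediation analysis with percentile bootstrap
#'
#' Mediator model m = a0 + a x; outcome model y = b0 + c' x + b m (OLS).
#' ACME = a*b (indirect effect), DE = c', total = c' + a*b, proportion
#' mediated = ACME / total. All quantities get seeded percentile bootstrap
#' confidence intervals over samples. When |total| falls below
#' 1e-3 * sd(y) the proportion is reported raw but flagged unstable.
#'
#' @param x exposure score (e.g. genomic risk score)
#' @param m mediator score (e.g. exposomic risk score)
#' @param y outcome (adjusted phenotype)
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param conf confidence level (default 0.95)
#' @return an object of class `mediation_fit`
#' @export
mediate_linear <- function(x, m, y, n_boot = 1000L, seed = 1L,
                           conf = 0.95) {
  n <- length(y)
  if (length(x) != n || length(m) != n)
    stop_omicreml("x, m, y must have equal length")
  if (n < 30) stop_omicreml("mediation needs n >= 30")
  if (any(!is.finite(c(x, m, y)))) stop_omicreml("non-finite input")
  if (stats::sd(x) == 0 || stats::sd(m) == 0)
    stop_omicreml("zero-variance exposure or mediator")

  point_est <- function(idx) {
    xi <- x[idx]; mi <- m[idx]; yi <- y[idx]
    a <- stats::cov(xi, mi) / stats::var(xi)
    cf <- stats::.lm.fit(cbind(1, xi, mi), yi)$coefficients
    c_prime <- cf[2]; b <- cf[3]
    acme <- a * b
    c(a = a, b = b, c_prime = c_prime, acme = acme, de = c_prime,
      total = c_prime + acme, prop_mediated = acme / (c_prime + acme))
  }
  est <- point_est(seq_len(n))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 61L))
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot))
    boot[b, ] <- point_est(sample.int(n, n, replace = TRUE))
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  rownames(ci) <- c("lower", "upper")

  structure(list(a = est[["a"]], b = est[["b"]], c_prime = est[["c_prime"]],
                 acme = est[["acme"]], de = est[["de"]],
                 total = est[["total"]],
                 prop_mediated = est[["prop_mediated"]],
                 prop_unstable = abs(est[["total"]]) < 1e-3 * stats::sd(y),
                 ci = ci, n_boot = n_boot, seed = seed, conf = conf,
                 n = n),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("mediation_fit (n =", x$n, ", bootstrap", x$n_boot, "reps)\n")
  for (q in c("acme", "de", "total", "prop_mediated"))
    cat(sprintf("  %-14s %-10s [%s, %s]\n", q, fmt6(x[[q]]),
                fmt6(x$ci["lower", q]), fmt6(x$ci["upper", q])))
  if (x$prop_unstable)
    cat("  (proportion mediated flagged: |total effect| near zero)\n")
  invisible(x)
}

#' Summarize mediation across cross-validation folds
#'
#' @param fits list of `mediation_fit`s, one per fold
#' @return list with `mean_prop`, `range_prop` (min, max) and a per-fold
#'   data.frame carrying point estimates and CIs
#' @export
summarize_cv_mediation <- function(fits) {
  if (length(fits) < 2) stop_omicreml("need >= 2 fold fits to summarize")
  for (f in fits) stopifnot(inherits(f, "mediation_fit"))
  props <- vapply(fits, function(f) f$prop_mediated, numeric(1))
  per_fold <- data.frame(
    fold = seq_along(fits),
    prop_mediated = props,
    ci_lower = vapply(fits, function(f) f$ci["lower", "prop_mediated"],
                      numeric(1)),
    ci_upper = vapply(fits, function(f) f$ci["upper", "prop_mediated"],
                      numeric(1)),
    acme = vapply(fits, function(f) f$acme, numeric(1)),
    total = vapply(fits, function(f) f$total, numeric(1)))
  structure(list(mean_prop = mean(props),
                 range_prop = range(props),
                 per_fold = per_fold),
            class = "cv_mediation_summary")
}

#' @export
print.cv_mediation_summary <- function(x, ...) {
  cat("CV mediation: mean proportion mediated =", fmt6(x$mean_prop),
      ", range [", fmt6(x$range_prop[1]), ",", fmt6(x$range_prop[2]), "]\n")
  invisible(x)
}
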