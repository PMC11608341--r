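# Variance-component estimation: multi-kernel GREML by average-information
# REML with EM warm-up, CORE-GREML covariance components, likelihood-ratio
# tests, variance proportions with delta-method SEs, and the GREML power
# calculator.
#
# The phenotypic covariance is
#   V(theta) = sum_i sigma2_i K_i + sum_p sigma12_p C_p + sigma2_e I
# with K_i the additive/interaction kernels, C_p = (S1 S2' + S2 S1')/2 the
# CORE-GREML covariance structures, and the restricted log-likelihood
#   logL = -1/2 ( log|V| + log|X'V^-1 X| + y'Py ),   P = V^-1 - V^-1 X
#          (X'V^-1 X)^-1 X'V^-1.
# Per iteration only one Cholesky of V is needed; traces tr(P M) are the
# elementwise sums sum(P * M), and the AI matrix uses only matrix-vector
# products, so cost is O(n^3) + O(q n^2) for q parameters.

#' Specify a variance-component model
#'
#' @param terms named list of `omic_kernel`s, one per additive or interaction
#'   random effect (names become parameter names)
#' @param cov_pairs optional list of covariance pairs, each created by
#'   [cov_pair()]
#' @return an object of class `variance_model`
#' @export
variance_model <- function(terms, cov_pairs = list()) {
  if (!length(terms)) terms <- list()
  if (length(terms)) {
    if (is.null(names(terms)) || any(names(terms) == ""))
      stop_omicreml("every term kernel must be named")
    check_unique_ids(names(terms), "term names")
    for (k in terms) stopifnot(inherits(k, "omic_kernel"))
    ref <- terms[[1]]
    for (k in terms) check_same_samples(ref, k)
  }
  for (p in cov_pairs) {
    if (!all(c(p$a, p$b) %in% names(terms)))
      stop_omicreml("cov_pair '", p$name, "' references undeclared terms")
    check_same_samples(terms[[1]], p$C)
  }
  cn <- vapply(cov_pairs, function(p) p$name, character(1))
  check_unique_ids(c(names(terms), cn), "parameter names")
  structure(list(terms = terms, cov_pairs = cov_pairs),
            class = "variance_model")
}

#' Declare a covariance component between two random effects
#'
#' If `C` is not supplied it is built from the two terms' kernels with
#' [covariance_structure()] (requires both to be PSD).
#'
#' @param name parameter name (e.g. "rG.E")
#' @param a,b names of the two terms the covariance links
#' @param C optional precomputed covariance-structure `omic_kernel`
#' @param terms the term list (needed when `C` is NULL)
#' @return a list describing the pair
#' @export
cov_pair <- function(name, a, b, C = NULL, terms = NULL) {
  if (is.null(C)) {
    if (is.null(terms) || !all(c(a, b) %in% names(terms)))
      stop_omicreml("cov_pair needs either C or the term kernels for ", a,
                    " and ", b)
    C <- covariance_structure(terms[[a]], terms[[b]])
  }
  list(name = name, a = a, b = b, C = C)
}

#' @export
print.variance_model <- function(x, ...) {
  cat("variance_model:", length(x$terms), "terms",
      if (length(x$cov_pairs)) paste0("+ ", length(x$cov_pairs), " cov pairs"),
      "+ residual\n")
  if (length(x$terms)) cat("  terms:", paste(names(x$terms), collapse = ", "), "\n")
  for (p in x$cov_pairs) cat("  cov:", p$name, "=", p$a, "~", p$b, "\n")
  invisible(x)
}

#' REML fitting options
#'
#' @param max_iter maximum iterations (default 100)
#' @param tol convergence tolerance on the change in restricted logL
#'   (default 1e-8); additionally the maximum relative parameter change must
#'   fall below 1e-6
#' @param em_steps number of EM warm-up iterations before switching to
#'   average-information updates (default 1)
#' @param var_floor_frac variance floor as a fraction of the phenotypic
#'   variance (default 1e-6); variance parameters are clamped there and
#'   flagged, GCTA-style
#' @param theta_init optional named initial parameter vector
#' @return a list of options
#' @export
reml_opts <- function(max_iter = 100L, tol = 1e-8, em_steps = 1L,
                      var_floor_frac = 1e-6, theta_init = NULL) {
  list(max_iter = as.integer(max_iter), tol = tol,
       em_steps = as.integer(em_steps), var_floor_frac = var_floor_frac,
       theta_init = theta_init)
}

# Cheap restricted logL at theta (one Cholesky, no P). Returns NULL if V or
# X'V^-1X fails to factor.
.reml_loglik_only <- function(theta, y, X, mats, n) {
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(mats)) if (theta[i] != 0)
    V <- V + theta[i] * mats[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  a <- backsolve(ch, y, transpose = TRUE)
  B <- backsolve(ch, X, transpose = TRUE)
  XtVX <- crossprod(B)
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  bb <- crossprod(B, a)
  yPy <- sum(a^2) - sum(backsolve(chX, bb, transpose = TRUE)^2)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
}

# Full evaluation: logL plus P, Py. NULL on factorization failure.
.reml_eval <- function(theta, y, X, mats, n) {
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(mats)) if (theta[i] != 0)
    V <- V + theta[i] * mats[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(chX) %*% t(VinvX)
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
  list(ll = ll, P = P, Py = Py)
}

# gradient and AI matrix from a full evaluation
.reml_derivs <- function(ev, mats, n, npar) {
  MPy <- matrix(0, n, npar)
  trPM <- numeric(npar)
  for (i in seq_len(npar - 1)) {
    MPy[, i] <- mats[[i]] %*% ev$Py
    trPM[i] <- sum(ev$P * mats[[i]])
  }
  MPy[, npar] <- ev$Py
  trPM[npar] <- sum(diag(ev$P))
  yPMPy <- colSums(ev$Py * MPy)
  grad <- -0.5 * (trPM - yPMPy)
  W <- ev$P %*% MPy
  AI <- 0.5 * crossprod(MPy, W)
  AI <- (AI + t(AI)) / 2
  list(grad = grad, AI = AI, trPM = trPM, yPMPy = yPMPy)
}

#' Fit a multi-kernel variance-component model by AI-REML
#'
#' Estimates one variance per term kernel, one covariance per declared pair,
#' and a residual variance, maximizing the restricted likelihood. The first
#' `em_steps` iterations use EM updates for stability, after which
#' average-information Newton steps with step-halving are taken. Variance
#' parameters are clamped at a small floor when they go negative (flagged in
#' `constrained`); covariance parameters are projected so each pair's 2x2
#' component matrix stays PSD (|sigma12| <= sqrt(s1^2 s2^2)).
#'
#' @param y numeric phenotype (already fixed-effect adjusted, or supply X)
#' @param X fixed-effect design matrix (default: intercept only)
#' @param model a `variance_model`
#' @param opts options from [reml_opts()]
#' @return an object of class `reml_fit` with elements `theta`, `se`,
#'   `logL`, `n_iter`, `converged`, `constrained`, `proportions`,
#'   `correlations`, `grad`, `AI`, `cov_theta`, `Vp`, plus the inputs needed
#'   for BLUP scoring
#' @export
reml_fit <- function(y, X = NULL, model, opts = reml_opts()) {
  stopifnot(inherits(model, "variance_model"))
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop_omicreml("nrow(X) != length(y)")
  if (stats::sd(y) == 0) stop_omicreml("phenotype has zero variance")
  if (length(model$terms) &&
      length(model$terms[[1]]$sample_ids) != n)
    stop_omicreml("kernel dimension (", length(model$terms[[1]]$sample_ids),
                  ") != length(y) (", n, ")")

  k <- length(model$terms)
  nc <- length(model$cov_pairs)
  npar <- k + nc + 1L
  qrX <- qr(X)
  if (n < npar + qrX$rank + 1)
    stop_omicreml("too few samples (", n, ") for ", npar, " parameters")

  mats <- c(lapply(model$terms, function(kk) kk$values),
            lapply(model$cov_pairs, function(p) p$C$values))
  par_names <- c(names(model$terms),
                 vapply(model$cov_pairs, function(p) p$name, character(1)),
                 "residual")
  is_var <- c(rep(TRUE, k), rep(FALSE, nc), TRUE)
  pair_a <- match(vapply(model$cov_pairs, function(p) p$a, character(1)),
                  par_names)
  pair_b <- match(vapply(model$cov_pairs, function(p) p$b, character(1)),
                  par_names)

  r0 <- qr.resid(qrX, y)
  Vp0 <- sum(r0^2) / (n - qrX$rank)
  floor_val <- opts$var_floor_frac * Vp0

  theta <- if (!is.null(opts$theta_init)) {
    ti <- opts$theta_init
    if (length(ti) != npar) stop_omicreml("theta_init must have ", npar,
                                          " entries")
    as.numeric(ti)
  } else {
    c(rep(Vp0 / (k + 1), k), rep(0, nc), Vp0 / (k + 1))
  }

  project <- function(th) {
    flags <- rep(FALSE, npar)
    low <- is_var & th <= floor_val
    th[low] <- floor_val; flags[low] <- TRUE
    for (p in seq_len(nc)) {
      j <- k + p
      bnd <- sqrt(th[pair_a[p]] * th[pair_b[p]])
      if (abs(th[j]) > bnd) { th[j] <- sign(th[j]) * bnd; flags[j] <- TRUE }
    }
    list(theta = th, flags = flags)
  }
  pr <- project(theta); theta <- pr$theta; flags <- pr$flags

  ev <- .reml_eval(theta, y, X, mats, n)
  if (is.null(ev)) stop_omicreml("singular V at initial parameters")

  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(opts$max_iter)) {
    n_iter <- iter
    d <- .reml_derivs(ev, mats, n, npar)
    if (iter <= opts$em_steps) {
      # EM update for variances; covariances unchanged during warm-up
      th_new <- theta
      iv <- which(is_var)
      th_new[iv] <- theta[iv] + theta[iv]^2 / n *
        (d$yPMPy[iv] - d$trPM[iv])
      pr <- project(th_new)
      ev_new <- .reml_eval(pr$theta, y, X, mats, n)
      if (is.null(ev_new)) stop_omicreml("singular V during EM step")
    } else {
      # active set: hold variance parameters clamped at the floor whose
      # gradient pushes further out, and solve the AI system on the rest
      held <- is_var & theta <= floor_val & d$grad < 0
      delta <- numeric(npar)
      free <- which(!held)
      dl <- tryCatch(solve(d$AI[free, free, drop = FALSE], d$grad[free]),
                     error = function(e) NULL)
      if (is.null(dl)) {
        # AI singular (aliased kernels): fall back to a scaled gradient step
        dl <- d$grad[free] / max(sum(abs(d$grad[free])), 1) * Vp0 * 0.01
      }
      delta[free] <- dl
      step <- 1
      for (h in 1:30) {
        pr_try <- project(theta + step * delta)
        ll_try <- .reml_loglik_only(pr_try$theta, y, X, mats, n)
        if (!is.null(ll_try) && ll_try >= ev$ll - 1e-12) {
          pr <- pr_try
          break
        }
        step <- step / 2
      }
      if (is.null(ll_try) || ll_try < ev$ll - 1e-12) {
        # no improving step found: stay put; converged if the free-parameter
        # gradient has vanished (KKT at the boundary)
        pr <- project(theta)
        converged <- max(abs(d$grad[!held])) < 1e-4
        theta <- pr$theta; flags <- pr$flags
        break
      }
      ev_new <- .reml_eval(pr$theta, y, X, mats, n)
    }
    dll <- ev_new$ll - ev$ll
    relch <- max(abs(pr$theta - theta) / pmax(abs(theta), 1e-6 * Vp0))
    theta <- pr$theta; flags <- pr$flags; ev <- ev_new
    if (iter > opts$em_steps && abs(dll) < opts$tol && relch < 1e-6) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge after ", n_iter, " iterations")

  d <- .reml_derivs(ev, mats, n, npar)
  cov_theta <- tryCatch(solve(d$AI), error = function(e) NULL)
  if (is.null(cov_theta) || any(!is.finite(diag(cov_theta))) ||
      any(diag(cov_theta) < 0)) {
    warning("average-information matrix is singular or indefinite; ",
            "standard errors unavailable (model may be unidentifiable)")
    cov_theta <- matrix(NA_real_, npar, npar)
    converged <- FALSE
  }
  se <- sqrt(diag(cov_theta))
  names(theta) <- names(se) <- par_names
  dimnames(cov_theta) <- list(par_names, par_names)
  names(flags) <- par_names

  Vp <- sum(theta[is_var])
  fit <- structure(list(
    theta = theta, se = se, logL = ev$ll, n_iter = n_iter,
    converged = converged, constrained = flags, grad = d$grad,
    AI = d$AI, cov_theta = cov_theta, Vp = Vp, n = n,
    par_names = par_names, is_var = is_var,
    model = model, y = y, X = X, opts = opts, var_floor = floor_val),
    class = "reml_fit")
  fit$proportions <- variance_proportions(fit)
  fit$correlations <- .reml_correlations(fit, pair_a, pair_b)
  fit
}

#' Fit a CORE-GREML model (variance components plus covariances)
#'
#' Identical engine to [reml_fit()]; this entry point simply requires at
#' least one covariance pair, matching the CORE-GREML usage.
#'
#' @inheritParams reml_fit
#' @return a `reml_fit`
#' @export
core_reml_fit <- function(y, X = NULL, model, opts = reml_opts()) {
  if (!length(model$cov_pairs))
    stop_omicreml("core_reml_fit requires at least one covariance pair; ",
                  "use reml_fit() otherwise")
  reml_fit(y, X, model, opts)
}

.reml_correlations <- function(fit, pair_a, pair_b) {
  nc <- length(fit$model$cov_pairs)
  if (!nc) return(NULL)
  k <- length(fit$model$terms)
  out <- data.frame(pair = character(nc), r = numeric(nc), se = numeric(nc),
                    stringsAsFactors = FALSE)
  for (p in seq_len(nc)) {
    j <- k + p; a <- pair_a[p]; b <- pair_b[p]
    va <- fit$theta[a]; vb <- fit$theta[b]; cc <- fit$theta[j]
    r <- cc / sqrt(va * vb)
    grd <- numeric(length(fit$theta))
    grd[j] <- 1 / sqrt(va * vb)
    grd[a] <- -r / (2 * va)
    grd[b] <- -r / (2 * vb)
    se <- if (all(is.finite(fit$cov_theta)))
      sqrt(drop(t(grd) %*% fit$cov_theta %*% grd)) else NA_real_
    out$pair[p] <- fit$par_names[j]; out$r[p] <- r; out$se[p] <- se
  }
  out
}

#' Variance proportions (h2-style fractions) with delta-method SEs
#'
#' h2_i = sigma2_i / sigma2_P with sigma2_P the sum of all variance
#' parameters including the residual (covariance parameters do not enter the
#' total). SEs propagate the full parameter covariance from the inverse AI
#' matrix through the first-order delta method.
#'
#' @param fit a `reml_fit`
#' @return data.frame with term, variance, se_variance, proportion, se
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  iv <- which(fit$is_var)
  Vp <- sum(fit$theta[iv])
  if (Vp <= 0) stop_omicreml("total phenotypic variance is not positive")
  out <- data.frame(term = fit$par_names[iv],
                    variance = fit$theta[iv],
                    se_variance = fit$se[iv],
                    proportion = fit$theta[iv] / Vp,
                    se = NA_real_, stringsAsFactors = FALSE)
  ok <- all(is.finite(fit$cov_theta))
  for (r in seq_along(iv)) {
    i <- iv[r]
    grd <- numeric(length(fit$theta))
    grd[iv] <- -fit$theta[i] / Vp^2
    grd[i] <- grd[i] + 1 / Vp
    if (ok) out$se[r] <- sqrt(drop(t(grd) %*% fit$cov_theta %*% grd))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit: n =", x$n, ", logL =", fmt6(x$logL),
      ", iters =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  pr <- x$proportions
  for (i in seq_len(nrow(pr)))
    cat(sprintf("  %-12s var = %-10s se = %-10s prop = %s\n", pr$term[i],
                fmt6(pr$variance[i]), fmt6(pr$se_variance[i]),
                fmt6(pr$proportion[i])))
  if (!is.null(x$correlations))
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("  %-12s r = %-10s se = %s\n", x$correlations$pair[i],
                  fmt6(x$correlations$r[i]), fmt6(x$correlations$se[i])))
  if (any(x$constrained)) cat("  constrained:",
                              paste(names(which(x$constrained)),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Lambda = 2 (logL_full - logL_reduced) referred to a chi-square with `df`
#' degrees of freedom, or to the boundary mixture 0.5*chisq_0 + 0.5*chisq_1
#' when testing a single variance component constrained to be non-negative
#' (`boundary = TRUE`, df must be 1).
#'
#' @param fit_full,fit_reduced `reml_fit`s on the same data, reduced nested
#'   in full
#' @param boundary use the 50:50 chi-square mixture (default FALSE)
#' @param df degrees of freedom (default: difference in parameter counts)
#' @return the p-value, with attributes `lambda` and `df`
#' @export
lrt <- function(fit_full, fit_reduced, boundary = FALSE, df = NULL) {
  stopifnot(inherits(fit_full, "reml_fit"), inherits(fit_reduced, "reml_fit"))
  if (fit_full$n != fit_reduced$n)
    stop_omicreml("fits are on different sample sizes")
  if (!all(fit_reduced$par_names %in% fit_full$par_names))
    stop_omicreml("models are not nested: reduced has parameters absent from full")
  if (is.null(df)) df <- length(fit_full$theta) - length(fit_reduced$theta)
  if (df < 1) stop_omicreml("full model has no extra parameters")
  lam <- 2 * (fit_full$logL - fit_reduced$logL)
  # slight inversions arise legitimately when a null component is clamped at
  # the small positive variance floor, so the tolerance is relative
  if (lam < -1e-6 * max(1, abs(fit_reduced$logL)))
    stop_omicreml("logL of full model is below reduced beyond tolerance (",
                  format(lam), "); check convergence")
  lam <- max(lam, 0)
  p <- if (boundary) {
    if (df != 1) stop_omicreml("boundary mixture is defined for df = 1")
    if (lam <= 0) 1 else 0.5 * stats::pchisq(lam, 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lam, df, lower.tail = FALSE)
  }
  attr(p, "lambda") <- lam
  attr(p, "df") <- df
  p
}

#' GREML power calculation
#'
#' Closed-form power of detecting a variance fraction h2 at sample size n,
#' given the variance of the off-diagonal relationship coefficients
#' (~2e-5 for unrelated genotyped samples): se_h2 = sqrt(2 / (n^2 *
#' var_offdiag)), non-centrality (h2/se)^2, power from the non-central
#' chi-square with 1 df at level alpha.
#'
#' @param n sample size (>= 2)
#' @param h2 variance fraction in (0, 1)
#' @param var_offdiag variance of off-diagonal kernel entries (default 2e-5)
#' @param alpha significance level (default 0.05)
#' @return list with `se_h2`, `ncp`, `power` (class `greml_power`)
#' @export
greml_power <- function(n, h2, var_offdiag = 2e-5, alpha = 0.05) {
  if (n < 2) stop_omicreml("n must be >= 2")
  if (h2 <= 0 || h2 >= 1) stop_omicreml("h2 must lie in (0, 1)")
  if (var_offdiag <= 0) stop_omicreml("var_offdiag must be positive")
  se_h2 <- sqrt(2 / (n^2 * var_offdiag))
  ncp <- (h2 / se_h2)^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  power <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  structure(list(se_h2 = se_h2, ncp = ncp, power = power, n = n, h2 = h2,
                 alpha = alpha),
            class = "greml_power")
}

#' @export
print.greml_power <- function(x, ...) {
  cat("GREML power: n =", x$n, ", h2 =", x$h2, "\n")
  cat("  se(h2) =", fmt6(x$se_h2), ", NCP =", fmt6(x$ncp),
      ", power =", fmt6(x$power), "at alpha =", x$alpha, "\n")
  invisible(x)
}
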