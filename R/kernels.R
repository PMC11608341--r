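# Relationship kernels: additive layer kernels (GRM/TRM/MRM/ERM), Hadamard
# interaction kernels, and the CORE-GREML covariance structures built from
# symmetric kernel square roots.

#' Construct a sample-similarity kernel
#'
#' An n x n symmetric matrix over a fixed sample ordering, tagged by the
#' layer or construction it represents. Additive and interaction kernels are
#' positive semi-definite; covariance structures (`psd = FALSE`) may be
#' indefinite.
#'
#' @param values symmetric numeric matrix
#' @param sample_ids sample identifiers matching the matrix order
#' @param tag label, e.g. "G", "T:coronary", "M", "E", "interaction:GxE",
#'   "covstruct:G.E"
#' @param psd logical; whether the kernel is required to be PSD
#' @param meta optional list of provenance metadata
#' @return an object of class `omic_kernel`
#' @export
omic_kernel <- function(values, sample_ids = rownames(values), tag = "K",
                        psd = TRUE, meta = list()) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop_omicreml("kernel must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  check_unique_ids(sample_ids, "sample ids")
  if (length(sample_ids) != n)
    stop_omicreml("sample_ids length does not match kernel dimension")
  sca <- max(abs(values), 1e-300)
  if (max(abs(values - t(values))) > 1e-10 * sca)
    stop_omicreml("kernel is not symmetric (tag ", tag, ")")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, tag = tag,
                 psd = psd, meta = meta),
            class = "omic_kernel")
}

#' @export
print.omic_kernel <- function(x, ...) {
  cat("omic_kernel [", x$tag, "]: ", length(x$sample_ids), " x ",
      length(x$sample_ids), ", mean diag = ",
      fmt6(mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.omic_kernel <- function(x) dim(x$values)

#' Subset a kernel to a set of samples (in the given order)
#' @param k an `omic_kernel`
#' @param samples sample ids or indices
#' @return an `omic_kernel`
#' @export
kernel_subset <- function(k, samples) {
  i <- if (is.character(samples)) match(samples, k$sample_ids) else samples
  if (anyNA(i)) stop_omicreml("unknown sample id in kernel subset")
  omic_kernel(k$values[i, i, drop = FALSE], k$sample_ids[i], tag = k$tag,
              psd = k$psd, meta = k$meta)
}

check_same_samples <- function(k1, k2) {
  if (length(k1$sample_ids) != length(k2$sample_ids))
    stop_omicreml("kernels have different sample counts: ",
                  length(k1$sample_ids), " vs ", length(k2$sample_ids))
  mism <- which(k1$sample_ids != k2$sample_ids)
  if (length(mism))
    stop_omicreml("kernel sample ids differ first at position ", mism[1],
                  ": '", k1$sample_ids[mism[1]], "' vs '",
                  k2$sample_ids[mism[1]], "'")
  invisible(TRUE)
}

#' Build a feature-based relationship kernel (TRM / MRM / ERM)
#'
#' Columns are centered and, by default, scaled to unit (population)
#' variance; the kernel is the average cross-product K = Z Z' / p over the p
#' retained features. Constant features carry no relational information and
#' are dropped with a recorded count.
#'
#' @param panel an `omics_panel`
#' @param standardize scale columns to unit variance (default TRUE)
#' @return an `omic_kernel` tagged from the panel layer
#' @export
feature_kernel <- function(panel, standardize = TRUE) {
  stopifnot(inherits(panel, "omics_panel"))
  Z <- panel$values
  mu <- colMeans(Z)
  Z <- sweep(Z, 2, mu)
  # population (1/n) variance so a single +-1 contrast yields unit diagonal
  v <- colMeans(Z^2)
  keep <- v > 0
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop_omicreml("all features constant in layer '", panel$layer, "'")
  Z <- Z[, keep, drop = FALSE]
  if (standardize) Z <- sweep(Z, 2, sqrt(v[keep]), "/")
  K <- tcrossprod(Z) / ncol(Z)
  omic_kernel(K, panel$sample_ids, tag = panel$layer, psd = TRUE,
              meta = list(n_features = ncol(Z), n_dropped_constant = n_dropped,
                          standardized = standardize))
}

#' Hadamard interaction kernel between two layers
#'
#' The elementwise product K1 * K2 models the multiplicative interaction of
#' the two random effects (e.g. gene-environment). By the Schur product
#' theorem the result is PSD when both inputs are. By default it is rescaled
#' to mean diagonal 1 so its variance component is on the same per-unit scale
#' as the additive terms.
#'
#' @param K1,K2 `omic_kernel`s over identical samples in identical order
#' @param normalize rescale so mean(diag) = 1 (default TRUE)
#' @return an `omic_kernel` tagged "interaction:<tag1>x<tag2>"
#' @export
interaction_kernel <- function(K1, K2, normalize = TRUE) {
  check_same_samples(K1, K2)
  K <- K1$values * K2$values
  meta <- list(parents = c(K1$tag, K2$tag))
  if (normalize) {
    md <- mean(diag(K))
    if (md <= 0) stop_omicreml("interaction kernel has nonpositive mean diagonal")
    K <- K / md
    meta$scale_factor <- md
  }
  omic_kernel(K, K1$sample_ids,
              tag = paste0("interaction:", K1$tag, "x", K2$tag),
              psd = TRUE, meta = meta)
}

#' Symmetric square root of a kernel
#'
#' Eigendecomposes K = U L U' and returns S = U sqrt(L) U' with S S' = K.
#' Tiny negative eigenvalues (numerical noise, >= -1e-8 * max) are clipped to
#' `eig_floor`; materially negative eigenvalues raise an error when
#' `require_psd` is TRUE, otherwise they are clipped too.
#'
#' @param K an `omic_kernel` (or plain symmetric matrix)
#' @param eig_floor value replacing clipped eigenvalues (default 0)
#' @param require_psd error on materially indefinite input (default: the
#'   kernel's own `psd` flag, TRUE for a bare matrix)
#' @return a plain numeric matrix S (symmetric)
#' @export
kernel_sqrt <- function(K, eig_floor = 0, require_psd = NULL) {
  if (inherits(K, "omic_kernel")) {
    if (is.null(require_psd)) require_psd <- K$psd
    M <- K$values
  } else {
    if (is.null(require_psd)) require_psd <- TRUE
    M <- as.matrix(K)
  }
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- 1e-8 * max(abs(lam), 1e-300)
  if (any(lam < -tol) && require_psd)
    stop_omicreml("kernel is materially indefinite (min eigenvalue ",
                  format(min(lam)), "); PSD required")
  lam[lam < tol] <- pmax(eig_floor, 0)
  S <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  (S + t(S)) / 2
}

#' CORE-GREML covariance structure between two kernels
#'
#' The coefficient matrix multiplying the covariance parameter sigma_12 in
#' the phenotypic covariance V: C = (S1 S2' + S2 S1') / 2 with S_i the
#' symmetric square root of K_i. C is symmetric by construction but not
#' necessarily PSD.
#'
#' @param K1,K2 PSD `omic_kernel`s over identical samples
#' @return an `omic_kernel` with tag "covstruct:<tag1>.<tag2>", `psd = FALSE`
#' @export
covariance_structure <- function(K1, K2) {
  check_same_samples(K1, K2)
  S1 <- kernel_sqrt(K1, require_psd = TRUE)
  S2 <- kernel_sqrt(K2, require_psd = TRUE)
  C <- (S1 %*% t(S2) + S2 %*% t(S1)) / 2
  omic_kernel(C, K1$sample_ids,
              tag = paste0("covstruct:", K1$tag, ".", K2$tag),
              psd = FALSE, meta = list(parents = c(K1$tag, K2$tag)))
}

#' Rescale a kernel to mean diagonal 1
#'
#' Keeps variance components comparable across layers: with mean(diag K) = 1
#' the component sigma^2 is directly the variance contributed per sample.
#'
#' @param K an `omic_kernel`
#' @return the rescaled `omic_kernel`; the factor is stored in `meta$trace_scale`
#' @export
trace_normalize <- function(K) {
  md <- mean(diag(K$values))
  if (md <= 0) stop_omicreml("mean diagonal must be positive to normalize")
  meta <- K$meta
  meta$trace_scale <- md
  omic_kernel(K$values / md, K$sample_ids, tag = K$tag, psd = K$psd,
              meta = meta)
}
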