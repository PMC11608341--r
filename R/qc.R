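# SNP- and sample-level quality control, GRM construction and relatedness
# pruning. Filters follow the GCTA/PLINK conventions: MAF < 1%, HWE
# P < 1e-7, call rate < 95%, info score < 60%, sample missingness > 5%,
# pairwise relatedness > 0.05.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df goodness-of-fit chi-square of observed genotype counts against the
#' expectations n*p^2, 2*n*p*q, n*q^2 under the estimated allele frequency.
#' Monomorphic sites (an expected class of zero) return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts
#' @return the HWE p-value
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0)) stop_omicreml("genotype counts must be non-negative")
  n <- sum(cnt)
  if (n < 1) stop_omicreml("need at least one genotyped sample")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) return(1.0)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((cnt - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' SNP-level quality control
#'
#' Removes SNPs failing any of: minor allele frequency below `maf_min`, HWE
#' p-value below `hwe_alpha`, call rate below `call_rate_min`, imputation
#' info score below `info_min`, or duplicate SNP id (first occurrence kept).
#' All statistics are computed once on the input panel; filters are not
#' re-estimated sequentially.
#'
#' @param panel a `snp_panel`
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param hwe_alpha HWE p-value threshold (default 1e-7)
#' @param call_rate_min minimum SNP call rate (default 0.95)
#' @param info_min minimum info score (default 0.60)
#' @return list with the filtered `panel` and a `report` (class `qc_report`)
#' @export
snp_qc <- function(panel, maf_min = 0.01, hwe_alpha = 1e-7,
                   call_rate_min = 0.95, info_min = 0.60) {
  stopifnot(inherits(panel, "snp_panel"))
  for (th in c(maf_min, call_rate_min, info_min))
    if (th <= 0 || th >= 1) stop_omicreml("QC thresholds must lie in (0,1)")
  X <- panel$dosages
  n <- nrow(X); m <- ncol(X)

  call_rate <- colMeans(!is.na(X))
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  hwe_p <- vapply(seq_len(m), function(k) {
    x <- X[, k]
    hwe_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
  }, numeric(1))

  fail_maf <- maf < maf_min | is.nan(maf)
  fail_hwe <- hwe_p < hwe_alpha
  fail_call <- call_rate < call_rate_min
  fail_info <- panel$snp_meta$info_score < info_min
  fail_dup <- duplicated(panel$snp_meta$id)

  drop <- fail_maf | fail_hwe | fail_call | fail_info | fail_dup
  if (all(drop))
    stop_omicreml("empty panel: all ", m, " SNPs removed by QC")

  report <- structure(list(
    axis = "snp", n_input = m, n_removed = sum(drop), n_retained = sum(!drop),
    removed_by = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                   call_rate = sum(fail_call), info = sum(fail_info),
                   duplicate_id = sum(fail_dup)),
    thresholds = c(maf_min = maf_min, hwe_alpha = hwe_alpha,
                   call_rate_min = call_rate_min, info_min = info_min)),
    class = "qc_report")
  list(panel = subset_panel(panel, snps = which(!drop)), report = report)
}

#' Sample-level quality control
#'
#' Removes samples whose genotype missing rate exceeds `miss_max`, plus any
#' samples flagged in `exclude_flags` (externally-determined exclusions such
#' as sex mismatch or aneuploidy, which are not computable from dosages and
#' are passed through as booleans).
#'
#' @param panel a `snp_panel`
#' @param miss_max maximum per-sample missing fraction (default 0.05)
#' @param exclude_flags optional logical vector (length n_samples)
#' @return list with the filtered `panel` and a `report`
#' @export
sample_qc <- function(panel, miss_max = 0.05, exclude_flags = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  X <- panel$dosages
  n <- nrow(X)
  miss <- rowMeans(is.na(X))
  fail_miss <- miss > miss_max
  fail_flag <- if (is.null(exclude_flags)) rep(FALSE, n) else as.logical(exclude_flags)
  if (length(fail_flag) != n)
    stop_omicreml("exclude_flags length != n_samples")
  drop <- fail_miss | fail_flag
  if (sum(!drop) < 2)
    stop_omicreml("empty panel: fewer than 2 samples retained by sample QC")
  report <- structure(list(
    axis = "sample", n_input = n, n_removed = sum(drop),
    n_retained = sum(!drop),
    removed_by = c(missingness = sum(fail_miss), flagged = sum(fail_flag)),
    thresholds = c(miss_max = miss_max)),
    class = "qc_report")
  list(panel = subset_panel(panel, samples = which(!drop)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$axis, "): ", x$n_input, " -> ", x$n_retained,
      " (removed ", x$n_removed, ")\n", sep = "")
  for (nm in names(x$removed_by))
    cat("  ", nm, ": ", x$removed_by[[nm]], "\n", sep = "")
  invisible(x)
}

#' Genomic relationship matrix (GCTA estimator)
#'
#' A_ij = (1/m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))
#' over the m polymorphic SNPs, with missing dosages mean-imputed to 2 p_k
#' (GCTA convention). Monomorphic SNPs are skipped and counted.
#'
#' @param panel a `snp_panel`
#' @return an `omic_kernel` tagged "G"; `meta$n_snps_used` and
#'   `meta$n_monomorphic` record the SNP accounting
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  X <- panel$dosages
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  if (sum(poly) < 1)
    stop_omicreml("no polymorphic SNPs; cannot compute GRM")
  X <- X[, poly, drop = FALSE]
  p <- p_hat[poly]
  # mean-impute missing to 2p, then center and scale by sqrt(2p(1-p))
  for (k in which(colSums(is.na(X)) > 0)) X[is.na(X[, k]), k] <- 2 * p[k]
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / ncol(W)
  omic_kernel(A, panel$sample_ids, tag = "G", psd = TRUE,
              meta = list(n_snps_used = ncol(W),
                          n_monomorphic = sum(!poly)))
}

#' Greedy relatedness pruning of a GRM
#'
#' While any off-diagonal |A_ij| exceeds `cutoff`, remove the sample in the
#' largest number of such pairs (ties broken by input order: the
#' earliest-indexed max-degree sample is removed). Mimics GCTA --grm-cutoff.
#'
#' @param grm an `omic_kernel`
#' @param cutoff maximum allowed |off-diagonal| (default 0.05)
#' @return character vector of retained sample ids, in input order
#' @export
relatedness_prune <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "omic_kernel"))
  A <- abs(grm$values)
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    over <- (A > cutoff) & outer(keep, keep, "&")
    deg <- rowSums(over)
    if (max(deg) == 0) break
    victim <- which(deg == max(deg))[1]
    keep[victim] <- FALSE
  }
  grm$sample_ids[keep]
}
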