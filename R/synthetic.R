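# Synthetic multi-omics generator with known ground truth: biallelic
# dosages, layer feature matrices, additive / interaction / covariance
# effects built through kernel square roots (the CORE-GREML generative
# model), and a liability-threshold ordinal phenotype.

.SIM_TERMS <- c("G", "T", "M", "E", "GxE", "TxE", "MxE", "GxT", "TxM",
                "residual")
.SIM_PAIRS <- c("rG.E", "rG.T", "rT.E", "rT.M", "rM.E")

#' Declare simulation ground truth
#'
#' Variance components are fractions of the total phenotypic (liability)
#' variance and must sum to 1. Covariances are raw sigma_12 values on the
#' same scale, each bounded by sqrt(sigma2_1 * sigma2_2) of its pair.
#'
#' @param var_components named numeric vector; names from
#'   G, T, M, E, GxE, TxE, MxE, GxT, TxM, residual
#' @param cov_components optional named numeric vector; names from
#'   rG.E, rG.T, rT.E, rT.M, rM.E
#' @param case_fraction fraction of samples coded as cases (default 0.095,
#'   the observed positive-test rate the generator emulates)
#' @param severe_fraction fraction of cases coded severe (default 0.5)
#' @param seed master integer seed
#' @return an object of class `sim_truth`
#' @export
sim_truth <- function(var_components, cov_components = NULL,
                      case_fraction = 0.095, severe_fraction = 0.5,
                      seed = 1L) {
  v <- unlist(var_components)
  bad <- setdiff(names(v), .SIM_TERMS)
  if (length(bad)) stop_omicreml("unknown variance term(s): ",
                                 paste(bad, collapse = ", "))
  if (any(v < 0)) stop_omicreml("variance components must be >= 0")
  if (abs(sum(v) - 1) > 1e-8)
    stop_omicreml("variance components must sum to 1 (got ", sum(v), ")")
  if (is.null(v["residual"]) || is.na(v["residual"]))
    stop_omicreml("a 'residual' component is required")
  cv <- if (is.null(cov_components)) numeric(0) else unlist(cov_components)
  bad <- setdiff(names(cv), .SIM_PAIRS)
  if (length(bad)) stop_omicreml("unknown covariance pair(s): ",
                                 paste(bad, collapse = ", "))
  for (nm in names(cv)) {
    ab <- strsplit(sub("^r", "", nm), ".", fixed = TRUE)[[1]]
    va <- v[ab[1]]; vb <- v[ab[2]]
    if (is.na(va) || is.na(vb))
      stop_omicreml("covariance ", nm, " requires additive terms ", ab[1],
                    " and ", ab[2])
    if (abs(cv[nm]) > sqrt(va * vb) + 1e-12)
      stop_omicreml("covariance ", nm, " = ", cv[nm],
                    " violates |s12| <= sqrt(s1^2 s2^2) = ",
                    sqrt(va * vb))
  }
  layers_in_pairs <- unlist(strsplit(sub("^r", "", names(cv)), ".",
                                     fixed = TRUE))
  if (anyDuplicated(layers_in_pairs))
    stop_omicreml("each layer may participate in at most one covariance pair")
  structure(list(var_components = v, cov_components = cv,
                 case_fraction = case_fraction,
                 severe_fraction = severe_fraction, seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate a biallelic SNP dosage panel
#'
#' Per-SNP allele frequencies are drawn uniformly in `maf_range`; dosages are
#' Binomial(2, p) independently per sample (no LD); missing entries are
#' masked completely at random at `missing_rate`.
#'
#' @param n_samples number of samples (>= 2)
#' @param n_snps number of SNPs
#' @param maf_range frequency interval, a sub-interval of (0, 0.5]
#' @param missing_rate fraction of entries set missing (in [0, 1))
#' @param seed integer seed (deterministic output)
#' @return a `snp_panel`; drawn frequencies are in `snp_meta$freq`
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L) {
  if (n_samples < 2) stop_omicreml("n_samples must be >= 2")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_omicreml("maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_omicreml("missing_rate must lie in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 1L))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  X <- matrix(stats::rbinom(n_samples * n_snps, 2, rep(p, each = n_samples)),
              n_samples, n_snps)
  if (missing_rate > 0) {
    X[stats::runif(length(X)) < missing_rate] <- NA
  }
  snp_panel(X, sample_ids = paste0("S", seq_len(n_samples)),
            snp_meta = data.frame(id = paste0("snp", seq_len(n_snps)),
                                  chr = 1L, pos = seq_len(n_snps),
                                  allele1 = "A", allele2 = "B",
                                  info_score = 1.0, freq = p,
                                  stringsAsFactors = FALSE))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Convert a continuous liability to ordinal 0/1/2 status
#'
#' The top `case_fraction` quantile of the liability is coded as cases
#' (>= 1); within cases the top `severe_fraction_of_cases` is coded 2.
#' Quantile cut-points; counts match the requested fractions to within
#' integer rounding, and code order never disagrees with liability order.
#'
#' @param liability numeric vector
#' @param case_fraction fraction of samples coded nonzero (in (0,1))
#' @param severe_fraction_of_cases fraction of cases coded 2 (in [0,1])
#' @return integer vector of codes 0/1/2
#' @export
liability_to_ordinal <- function(liability, case_fraction = 0.095,
                                 severe_fraction_of_cases = 0.5) {
  n <- length(liability)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_omicreml("case_fraction must lie in (0, 1)")
  if (severe_fraction_of_cases < 0 || severe_fraction_of_cases > 1)
    stop_omicreml("severe_fraction_of_cases must lie in [0, 1]")
  if (stats::sd(liability) == 0)
    stop_omicreml("constant liability: thresholds undefined")
  n_case <- round(case_fraction * n)
  n_sev <- round(severe_fraction_of_cases * n_case)
  o <- order(liability, decreasing = TRUE)
  code <- integer(n)
  if (n_case > 0) code[o[seq_len(n_case)]] <- 1L
  if (n_sev > 0) code[o[seq_len(n_sev)]] <- 2L
  code
}

# stream registry so every random draw has its own reproducible sub-stream
.sim_stream <- function(what) {
  base <- c(genotypes = 1L, layer_T = 11L, layer_M = 12L, layer_E = 13L,
            eff_G = 21L, eff_T = 22L, eff_M = 23L, eff_E = 24L,
            eff_GxE = 25L, eff_TxE = 26L, eff_MxE = 27L, eff_GxT = 28L,
            eff_TxM = 29L, residual = 40L)
  s <- base[what]
  if (is.na(s)) stop_omicreml("unknown stream: ", what)
  s
}

#' Simulate a full multi-omics dataset with known ground truth
#'
#' Generates a genotype panel and continuous layer panels, builds the layer
#' kernels, then draws effect vectors through symmetric kernel square roots:
#' additive effects g_i = sigma_i S_i z_i; a covariance sigma_12 between two
#' layers is induced by sharing latent normals (g_2 = S_2 (rho sigma_2 z_1 +
#' sqrt(1-rho^2) sigma_2 z_2), the CORE-GREML structure); interaction
#' effects use the square root of the Hadamard kernel. The liability is the
#' sum of effects plus Gaussian residual, and the ordinal status applies
#' quantile thresholds.
#'
#' @param n_samples number of samples
#' @param truth a `sim_truth`
#' @param layer_sizes named feature counts; defaults mirror the emulated
#'   study scaled to desk size: c(G = 5000, T = 1634, M = 249, E = 43)
#' @param maf_range frequency interval for genotypes
#' @param genetic_corr optional named vector (T/M/E) in [0,1): fraction of
#'   each layer feature's variance driven linearly by a random subset of SNP
#'   dosages, giving feature-level genetic correlation a mechanistic origin
#'   (default 0: iid normal features)
#' @return an object of class `multiomics_sim`: the panels, all kernels,
#'   the continuous `liability`, ordinal `status`, realized `effects` per
#'   term (ground truth for recovery tests), and the `truth` used
#' @export
simulate_multiomics <- function(n_samples, truth,
                                layer_sizes = c(G = 5000, T = 1634,
                                                M = 249, E = 43),
                                maf_range = c(0.05, 0.5),
                                genetic_corr = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  v <- truth$var_components
  cv <- truth$cov_components
  seed <- truth$seed
  terms <- setdiff(names(v)[v > 0], "residual")
  # also keep zero-variance additive terms that anchor a covariance pair
  add_layers <- unique(unlist(c(
    lapply(terms, function(t) strsplit(t, "x")[[1]]),
    lapply(names(cv), function(nm) strsplit(sub("^r", "", nm), ".",
                                            fixed = TRUE)[[1]]))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  geno <- NULL
  kernels <- list()
  omics <- list()
  if ("G" %in% add_layers) {
    geno <- simulate_genotypes(n_samples, layer_sizes[["G"]],
                               maf_range = maf_range, seed = seed)
    kernels$G <- trace_normalize(compute_grm(geno))
  }
  layer_tag <- c(T = "transcriptome:sim", M = "metabolome", E = "exposome")
  for (ly in intersect(c("T", "M", "E"), add_layers)) {
    set.seed(sub_seed(seed, .sim_stream(paste0("layer_", ly))))
    p <- layer_sizes[[ly]]
    Z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    gc <- if (!is.null(genetic_corr)) genetic_corr[ly] else NA
    if (!is.na(gc) && gc > 0) {
      if (is.null(geno))
        stop_omicreml("genetic_corr for layer ", ly, " requires a G layer")
      nsub <- min(50L, ncol(geno$dosages))
      for (j in seq_len(p)) {
        idx <- sample.int(ncol(geno$dosages), nsub)
        w <- stats::rnorm(nsub)
        gpart <- drop(geno$dosages[, idx, drop = FALSE] %*% w)
        gpart <- (gpart - mean(gpart)) / max(stats::sd(gpart), 1e-12)
        Z[, j] <- sqrt(gc) * gpart + sqrt(1 - gc) * Z[, j]
      }
    }
    omics[[ly]] <- omics_panel(Z, sample_ids = paste0("S", seq_len(n_samples)),
                               feature_ids = paste0(ly, "_f", seq_len(p)),
                               layer = layer_tag[[ly]])
    kernels[[ly]] <- trace_normalize(feature_kernel(omics[[ly]]))
  }
  for (tm in terms[grepl("x", terms)]) {
    ab <- strsplit(tm, "x")[[1]]
    kernels[[tm]] <- interaction_kernel(kernels[[ab[1]]], kernels[[ab[2]]])
  }

  sqrts <- lapply(kernels, kernel_sqrt)
  # latent standard normals per term, from per-term streams
  zs <- list()
  for (tm in names(kernels)) {
    set.seed(sub_seed(seed, .sim_stream(paste0("eff_", tm))))
    zs[[tm]] <- stats::rnorm(n_samples)
  }
  effects <- list()
  paired <- character(0)
  for (nm in names(cv)) {              # covariance pairs share latents
    ab <- strsplit(sub("^r", "", nm), ".", fixed = TRUE)[[1]]
    a <- ab[1]; b <- ab[2]
    sa <- sqrt(v[[a]]); sb <- sqrt(v[[b]])
    if (sa == 0 || sb == 0)
      stop_omicreml("covariance ", nm, " needs positive variances for ", a,
                    " and ", b)
    rho <- cv[[nm]] / (sa * sb)
    effects[[a]] <- sa * drop(sqrts[[a]] %*% zs[[a]])
    effects[[b]] <- drop(sqrts[[b]] %*%
                           (rho * sb * zs[[a]] + sqrt(1 - rho^2) * sb * zs[[b]]))
    paired <- c(paired, a, b)
  }
  for (tm in setdiff(names(kernels), paired)) {
    s2 <- v[tm]
    if (is.na(s2) || s2 == 0) next
    effects[[tm]] <- sqrt(s2) * drop(sqrts[[tm]] %*% zs[[tm]])
  }
  set.seed(sub_seed(seed, .sim_stream("residual")))
  eps <- stats::rnorm(n_samples, sd = sqrt(v[["residual"]]))
  liability <- eps
  for (e in effects) liability <- liability + e
  status <- liability_to_ordinal(liability, truth$case_fraction,
                                 truth$severe_fraction)
  structure(list(geno = geno, omics = omics, kernels = kernels,
                 liability = liability, status = status,
                 sample_ids = paste0("S", seq_len(n_samples)),
                 effects = effects, residual = eps, truth = truth),
            class = "multiomics_sim")
}

#' @export
print.multiomics_sim <- function(x, ...) {
  cat("multiomics_sim: n =", length(x$liability), "; kernels:",
      paste(names(x$kernels), collapse = ", "), "\n")
  cat("  cases:", sum(x$status >= 1), "(severe:", sum(x$status == 2), ")\n")
  invisible(x)
}
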