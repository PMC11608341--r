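# Ordinal disease coding and fixed-effect pre-adjustment.

#' Encode ordinal disease status (0 = control, 1 = moderate, 2 = severe)
#'
#' Follows the WHO-style ordinal classification: severe cases (code 2) are
#' positives who were hospitalized, needed ICU admission / respiratory
#' support, or died with the disease as primary cause; moderate cases
#' (code 1) are all other positives, including clinically diagnosed or
#' self-quarantined individuals; controls (code 0) tested negative.
#'
#' @param records data.frame of per-sample logical flags: `tested_positive`,
#'   `hospitalized`, `icu_or_respiratory_support`, `died_covid_primary`,
#'   `clinically_diagnosed_or_quarantined` (missing columns default FALSE)
#' @return integer vector of codes in {0, 1, 2}
#' @export
encode_status <- function(records) {
  records <- as.data.frame(records)
  getf <- function(nm) {
    v <- records[[nm]] %||% rep(FALSE, nrow(records))
    if (!is.logical(v)) stop_omicreml("flag '", nm, "' must be logical")
    v & !is.na(v)
  }
  pos_test <- getf("tested_positive")
  diag_q <- getf("clinically_diagnosed_or_quarantined")
  severe <- getf("hospitalized") | getf("icu_or_respiratory_support") |
    getf("died_covid_primary")
  positive <- pos_test | diag_q
  bad <- severe & !positive
  if (any(bad))
    stop_omicreml("contradictory record(s): severity flag without positivity at row(s) ",
                  paste(utils::head(which(bad), 5), collapse = ", "))
  as.integer(ifelse(positive & severe, 2L, ifelse(positive, 1L, 0L)))
}

#' Pre-adjust the phenotype for fixed-effect factors
#'
#' Ordinary least squares of the numeric 0/1/2 status on dummy-coded
#' categorical covariates (e.g. genotyping batch and assessment centre) with
#' an intercept; returns the residuals, optionally standardized to unit
#' variance so downstream variance components read as fractions of the
#' adjusted phenotypic variance.
#'
#' @param y numeric (ordinal treated as numeric) phenotype vector
#' @param factors data.frame of categorical covariates (may be NULL/empty:
#'   intercept-only adjustment, i.e. centering)
#' @param standardize divide residuals by their standard deviation
#'   (default TRUE); skipped with a warning if residuals are all zero
#' @return numeric residual vector
#' @export
adjust_phenotype <- function(y, factors = NULL, standardize = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop_omicreml("phenotype contains NA")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(factors) && length(factors)) {
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
    if (nrow(factors) != n) stop_omicreml("factors rows != length(y)")
    for (nm in names(factors)) {
      f <- factor(factors[[nm]])
      if (anyNA(f)) stop_omicreml("factor '", nm, "' has missing levels")
      if (nlevels(f) < 2) {
        warning("dropping single-level factor '", nm, "'")
        next
      }
      D <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0(nm, levels(f)[-1])
      X <- cbind(X, D)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_omicreml("rank-deficient design; aliased columns: ",
                  paste(aliased, collapse = ", "))
  }
  r <- qr.resid(qrX, y)
  # a saturated design leaves only floating-point noise; treat as zero
  eps <- 1e-10 * max(stats::sd(y), 1)
  if (stats::sd(r) <= eps) {
    warning("residuals have zero variance; standardization skipped")
    return(rep(0, n))
  }
  if (standardize) r <- r / stats::sd(r)
  r
}
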