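# File formats: GCTA binary GRM triplets, PLINK .raw additive dosage text,
# TSV panels/phenotypes, GCTA-style .hsq result files and JSON run configs.

#' Write a kernel in GCTA binary GRM format
#'
#' Produces `<prefix>.grm.bin` (lower triangle including the diagonal,
#' row-major, 4-byte little-endian floats), `<prefix>.grm.N.bin` (pair
#' counts, same layout and type) and `<prefix>.grm.id` (tab-separated
#' FID/IID, here both the sample id).
#'
#' @param kernel an `omic_kernel`
#' @param prefix output path prefix
#' @param n_obs per-pair observation count written to .grm.N.bin (default:
#'   `meta$n_snps_used` if present, else 1)
#' @return invisibly, the prefix
#' @export
write_gcta_grm <- function(kernel, prefix, n_obs = NULL) {
  stopifnot(inherits(kernel, "omic_kernel"))
  n <- length(kernel$sample_ids)
  if (is.null(n_obs)) n_obs <- kernel$meta$n_snps_used %||% 1
  tri <- kernel$values[upper.tri(kernel$values, diag = TRUE)]
  # upper.tri of a symmetric matrix in column order == lower triangle rows
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_obs), length(tri)), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(kernel$sample_ids, kernel$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a kernel from GCTA binary GRM format
#'
#' @param prefix path prefix of the .grm.bin/.grm.N.bin/.grm.id triplet
#' @param tag tag for the resulting kernel (default "G")
#' @return an `omic_kernel`
#' @export
read_gcta_grm <- function(prefix, tag = "G") {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  if (!file.exists(idf) || !file.exists(binf))
    stop_omicreml("missing GRM file(s) at prefix ", prefix)
  ids <- utils::read.table(idf, sep = "\t", stringsAsFactors = FALSE)
  n <- nrow(ids)
  expected <- n * (n + 1) / 2
  sz <- file.info(binf)$size
  found <- sz / 4
  if (found != expected)
    stop_omicreml(".grm.bin size mismatch: expected ", expected,
                  " elements for ", n, " ids, found ", found)
  con <- file(binf, "rb")
  tri <- readBin(con, "numeric", n = expected, size = 4, endian = "little")
  close(con)
  M <- matrix(0, n, n)
  M[upper.tri(M, diag = TRUE)] <- tri
  d <- diag(M)
  M <- M + t(M)
  diag(M) <- d
  nobs <- NULL
  nbf <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nbf)) {
    con <- file(nbf, "rb")
    nobs <- readBin(con, "numeric", n = expected, size = 4,
                    endian = "little")
    close(con)
  }
  omic_kernel(M, ids[[2]], tag = tag, psd = TRUE,
              meta = list(n_snps_used = if (length(nobs)) nobs[1] else NA))
}

#' Read a PLINK .raw additive dosage file
#'
#' Expects the standard header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' one column per SNP named `<id>_<allele>`; entries 0/1/2 count the coded
#' allele, NA is missing.
#'
#' @param path file path
#' @return a `snp_panel`; the coded allele is recorded in
#'   `snp_meta$allele1`
#' @export
read_plink_raw <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_omicreml("empty file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  hdr <- toks[[1]]
  if (length(hdr) < 7 ||
      !identical(hdr[1:6], c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
    stop_omicreml("not a PLINK .raw header (expected FID IID PAT MAT SEX ",
                  "PHENOTYPE ...)")
  snp_cols <- hdr[-(1:6)]
  m <- length(snp_cols)
  n <- length(lines) - 1L
  ids <- character(n)
  X <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    row <- toks[[i + 1]]
    if (length(row) != length(hdr))
      stop_omicreml("ragged row at line ", i + 1, ": expected ",
                    length(hdr), " fields, found ", length(row))
    ids[i] <- row[2]
    vals <- row[-(1:6)]
    na <- vals == "NA"
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!na & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad))
      stop_omicreml("non-integer dosage '", vals[bad[1]], "' at line ",
                    i + 1, ", SNP column ", snp_cols[bad[1]])
    num[na] <- NA
    X[i, ] <- num
  }
  snp_id <- sub("_[^_]*$", "", snp_cols)
  allele <- sub("^.*_", "", snp_cols)
  snp_panel(X, sample_ids = ids,
            snp_meta = data.frame(id = snp_id, allele1 = allele,
                                  allele2 = "?", info_score = 1.0,
                                  stringsAsFactors = FALSE))
}

#' Write a SNP panel as PLINK .raw additive dosage text
#'
#' @param panel a `snp_panel`
#' @param path output file path
#' @return invisibly, the path
#' @export
write_plink_raw <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(panel$snp_meta$id, "_", panel$snp_meta$allele1))
  lines <- c(paste(hdr, collapse = " "))
  X <- panel$dosages
  for (i in seq_len(nrow(X))) {
    vals <- X[i, ]
    sv <- ifelse(is.na(vals), "NA", format(vals, trim = TRUE))
    lines <- c(lines, paste(c(panel$sample_ids[i], panel$sample_ids[i],
                              "0", "0", "0", "-9", sv), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an omics panel (or any sample x feature matrix) as TSV
#'
#' Header row = feature ids, first column = sample id.
#' @param panel an `omics_panel`
#' @param path output path
#' @return invisibly, the path
#' @export
write_omics_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "omics_panel"))
  df <- data.frame(sample_id = panel$sample_ids, panel$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an omics panel from TSV (first column sample id, header features)
#'
#' @param path input path
#' @param layer layer label for the panel
#' @return an `omics_panel`
#' @export
read_omics_tsv <- function(path, layer = "omics") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  omics_panel(as.matrix(df[, -1, drop = FALSE]),
              sample_ids = as.character(df[[1]]),
              feature_ids = colnames(df)[-1], layer = layer)
}

#' Write a phenotype table (sample id, status, optional covariates) as TSV
#' @param sample_ids sample identifiers
#' @param status ordinal status codes
#' @param covariates optional data.frame of per-sample covariates
#' @param path output path
#' @return invisibly, the path
#' @export
write_phenotype_tsv <- function(sample_ids, status, covariates = NULL,
                                path) {
  df <- data.frame(sample_id = sample_ids, status = status)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a REML fit as a GCTA-style .hsq text file
#'
#' Deterministic layout: Source/Variance/SE rows for every component, Vp,
#' per-term V(term)/Vp proportions, logL, n, convergence flag; all numbers
#' at 6 significant digits.
#'
#' @param fit a `reml_fit`
#' @param path output path
#' @return invisibly, the path
#' @export
write_hsq <- function(fit, path) {
  stopifnot(inherits(fit, "reml_fit"))
  pr <- fit$proportions
  lines <- "Source\tVariance\tSE"
  for (i in seq_len(nrow(pr)))
    lines <- c(lines, paste(paste0("V(", pr$term[i], ")"),
                            fmt6(pr$variance[i]), fmt6(pr$se_variance[i]),
                            sep = "\t"))
  if (!is.null(fit$correlations))
    for (i in seq_len(nrow(fit$correlations)))
      lines <- c(lines, paste(paste0("C(", fit$correlations$pair[i], ")"),
                              fmt6(fit$theta[fit$correlations$pair[i]]),
                              fmt6(fit$se[fit$correlations$pair[i]]),
                              sep = "\t"))
  lines <- c(lines, paste("Vp", fmt6(fit$Vp), "", sep = "\t"))
  for (i in seq_len(nrow(pr)))
    lines <- c(lines, paste(paste0("V(", pr$term[i], ")/Vp"),
                            fmt6(pr$proportion[i]), fmt6(pr$se[i]),
                            sep = "\t"))
  lines <- c(lines,
             paste("logL", fmt6(fit$logL), "", sep = "\t"),
             paste("n", fit$n, "", sep = "\t"),
             paste("converged", if (fit$converged) "yes" else "no", "",
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize simulation truth / run configuration as JSON
#' @param x a `sim_truth` or plain list
#' @param path output path
#' @return invisibly, the path
#' @export
write_config_json <- function(x, path) {
  # named atomic vectors must become objects, not bare arrays, in JSON
  listify <- function(v) {
    if (is.list(v)) lapply(v, listify)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  jsonlite::write_json(listify(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a JSON configuration
#' @param path input path
#' @return a list
#' @export
read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
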