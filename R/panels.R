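# Sample-by-feature containers for the genotype layer and the continuous
# omics layers (transcriptome / metabolome / exposome).

#' Construct a SNP dosage panel
#'
#' Holds an additive dosage matrix (samples x SNPs, entries 0/1/2 or NA) with
#' per-SNP metadata, the unit of input for quality control and GRM
#' construction.
#'
#' @param dosages numeric matrix, n_samples x n_snps, entries in {0,1,2,NA}
#' @param sample_ids character vector of unique sample identifiers
#' @param snp_meta data.frame with one row per SNP: columns `id`, `chr`,
#'   `pos`, `allele1`, `allele2`, `info_score` (imputation quality in [0,1]).
#'   Missing columns are filled with defaults.
#' @return an object of class `snp_panel`
#' @export
snp_panel <- function(dosages, sample_ids = rownames(dosages),
                      snp_meta = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (n < 2) stop_omicreml("snp_panel needs n_samples >= 2")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop_omicreml("sample_ids length (", length(sample_ids),
                  ") != n_samples (", n, ")")
  check_unique_ids(sample_ids, "sample ids")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop_omicreml("dosage entries must be 0, 1, 2 or NA; first offending value: ",
                  dosages[which(bad)[1]])
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(id = colnames(dosages) %||% paste0("snp", seq_len(m)),
                           stringsAsFactors = FALSE)
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  if (is.null(snp_meta$id)) snp_meta$id <- paste0("snp", seq_len(m))
  if (nrow(snp_meta) != m)
    stop_omicreml("snp_meta rows (", nrow(snp_meta), ") != n_snps (", m, ")")
  check_unique_ids(snp_meta$id, "SNP ids")
  if (is.null(snp_meta$chr)) snp_meta$chr <- 1L
  if (is.null(snp_meta$pos)) snp_meta$pos <- seq_len(m)
  if (is.null(snp_meta$allele1)) snp_meta$allele1 <- "A"
  if (is.null(snp_meta$allele2)) snp_meta$allele2 <- "B"
  if (is.null(snp_meta$info_score)) snp_meta$info_score <- 1.0
  storage.mode(dosages) <- "double"
  dimnames(dosages) <- list(sample_ids, snp_meta$id)
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 snp_meta = snp_meta),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", length(x$sample_ids), "samples x",
      nrow(x$snp_meta), "SNPs;",
      sum(is.na(x$dosages)), "missing dosages\n")
  invisible(x)
}

#' @export
dim.snp_panel <- function(x) dim(x$dosages)

#' Subset a SNP panel by samples and/or SNPs
#' @param x a `snp_panel`
#' @param samples sample ids or indices to keep (default all)
#' @param snps SNP ids or indices to keep (default all)
#' @param ... unused
#' @return a `snp_panel`
#' @export
subset_panel <- function(x, samples = NULL, snps = NULL, ...) {
  UseMethod("subset_panel")
}

#' @export
subset_panel.snp_panel <- function(x, samples = NULL, snps = NULL, ...) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  ki <- if (is.null(snps)) seq_len(nrow(x$snp_meta)) else
    if (is.character(snps)) match(snps, x$snp_meta$id) else snps
  if (anyNA(si)) stop_omicreml("unknown sample id in subset")
  if (anyNA(ki)) stop_omicreml("unknown SNP id in subset")
  snp_panel(x$dosages[si, ki, drop = FALSE],
            sample_ids = x$sample_ids[si],
            snp_meta = x$snp_meta[ki, , drop = FALSE])
}

#' Construct a continuous omics feature panel
#'
#' One layer of continuous features per sample: a transcriptome tissue
#' ("transcriptome:<tissue>"), the metabolome ("metabolome") or the exposome
#' ("exposome").
#'
#' @param values numeric matrix, n_samples x n_features
#' @param sample_ids unique sample identifiers
#' @param feature_ids unique feature identifiers
#' @param layer layer label, e.g. "metabolome" or "transcriptome:coronary"
#' @return an object of class `omics_panel`
#' @export
omics_panel <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values),
                        layer = "omics") {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (p < 1) stop_omicreml("omics_panel needs >= 1 feature")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  check_unique_ids(sample_ids, "sample ids")
  check_unique_ids(feature_ids, "feature ids")
  if (length(sample_ids) != n || length(feature_ids) != p)
    stop_omicreml("id lengths do not match matrix dimensions")
  if (any(!is.finite(values)))
    stop_omicreml("omics_panel values must be finite")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, layer = layer),
            class = "omics_panel")
}

#' @export
print.omics_panel <- function(x, ...) {
  cat("omics_panel [", x$layer, "]: ", length(x$sample_ids), " samples x ",
      length(x$feature_ids), " features\n", sep = "")
  invisible(x)
}

#' @export
subset_panel.omics_panel <- function(x, samples = NULL, snps = NULL, ...) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  if (anyNA(si)) stop_omicreml("unknown sample id in subset")
  omics_panel(x$values[si, , drop = FALSE], sample_ids = x$sample_ids[si],
              feature_ids = x$feature_ids, layer = x$layer)
}
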