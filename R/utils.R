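# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Distinct
#' components (genotypes, each omics layer, each effect vector, residuals,
#' fold assignment, bootstrap) draw from sub-streams indexed by a small
#' integer, so any sub-stream can be reproduced without replaying the others.
#' The mixing keeps every derived seed in [1, 2^31 - 2].
#'
#' @param seed master integer seed
#' @param stream non-negative integer stream index
#' @return an integer seed
#' @keywords internal
sub_seed <- function(seed, stream) {
  seed <- as.numeric(seed)
  stream <- as.numeric(stream)
  # split into halves so products stay well inside double precision
  lo <- seed %% 65536
  hi <- seed %/% 65536
  s <- (lo * 9973 + hi * 7039 + stream * 7919 + 1) %% 2147483646
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_omicreml <- function(...) stop(..., call. = FALSE)

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids))
    stop_omicreml("duplicate ", what, ": ",
                  paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                        collapse = ", "))
  invisible(ids)
}

# format a number at 6 significant digits for text output
fmt6 <- function(x) formatC(x, digits = 6, format = "g")
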