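# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed from a top-level seed
#'
#' One top-level seed drives all generators; each generator (and each sample
#' within a generator) gets its own deterministic child stream so that adding
#' a modality does not perturb the others.
#'
#' @param seed integer top-level seed.
#' @param stream integer stream index (any non-negative integer).
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L, is.finite(seed), is.finite(stream))
  # linear congruential mix modulo a prime < 2^31; keeps values in int range
  as.integer((abs(as.numeric(seed)) * 48271 + abs(as.numeric(stream)) * 1299721 + 1) %%
               2147483629)
}

chrom_norm <- function(chrom) sub("^chr", "", as.character(chrom))

is_autosome <- function(chrom) {
  cn <- chrom_norm(chrom)
  num <- grepl("^[0-9]+$", cn)
  out <- rep(FALSE, length(cn))
  out[num] <- as.integer(cn[num]) >= 1L & as.integer(cn[num]) <= 22L
  out
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_matrix_design <- function(mat, design) {
  if (is.null(colnames(mat)))
    stop_invalid("matrix must have sample_id column names")
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing))
    stop_invalid("samples absent from design: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
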