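# TSV/BED readers and writers.  Dialect: tab-separated, header row, UTF-8,
# '.' decimal; BED is 0-based half-open.

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write / read a per-sample SNP-array track
#'
#' Columns: probe_id, chrom, pos, lrr, baf, genotype.
#' @param track track data.frame.
#' @param path file path.
#' @export
write_snp_track <- function(track, path) write_tsv(track, path)

#' @rdname write_snp_track
#' @export
read_snp_track <- function(path) {
  tr <- read_tsv(path)
  need <- c("probe_id", "chrom", "pos", "lrr", "baf", "genotype")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop_invalid("SNP track lacks columns: ", paste(miss, collapse = ", "))
  tr$chrom <- as.character(tr$chrom)
  tr[order(match(tr$chrom, unique(tr$chrom)), tr$pos), , drop = FALSE]
}

#' Write / read an expression matrix with flags
#'
#' Layout: probe_id, symbol, then one `<sample>` intensity column and one
#' `<sample>.flag` column per sample.
#' @param expr list with `intensity`, `flags`, `annotation` (as returned
#'   by [generate_expression()]).
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  samples <- colnames(expr$intensity)
  out <- data.frame(probe_id = rownames(expr$intensity),
                    symbol = expr$annotation$symbol[
                      match(rownames(expr$intensity),
                            expr$annotation$probe_id)],
                    stringsAsFactors = FALSE)
  for (s in samples) {
    out[[s]] <- expr$intensity[, s]
    out[[paste0(s, ".flag")]] <- expr$flags[, s]
  }
  write_tsv(out, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  x <- read_tsv(path)
  flag_cols <- grep("\\.flag$", names(x), value = TRUE)
  samples <- sub("\\.flag$", "", flag_cols)
  intensity <- as.matrix(x[, samples, drop = FALSE])
  flags <- as.matrix(x[, flag_cols, drop = FALSE])
  rownames(intensity) <- rownames(flags) <- x$probe_id
  colnames(flags) <- samples
  list(intensity = intensity, flags = flags,
       annotation = data.frame(probe_id = x$probe_id, symbol = x$symbol,
                               stringsAsFactors = FALSE))
}

#' Write / read a beta matrix with detection P values
#'
#' Layout: probe_id, then one `<sample>` beta column and one
#' `<sample>.detp` column per sample.
#' @param beta probe x sample beta matrix.
#' @param detection_p probe x sample detection P matrix.
#' @param path file path.
#' @export
write_beta_matrix <- function(beta, detection_p, path) {
  out <- data.frame(probe_id = rownames(beta), stringsAsFactors = FALSE)
  for (s in colnames(beta)) {
    out[[s]] <- beta[, s]
    out[[paste0(s, ".detp")]] <- detection_p[, s]
  }
  write_tsv(out, path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  x <- read_tsv(path)
  detp_cols <- grep("\\.detp$", names(x), value = TRUE)
  samples <- sub("\\.detp$", "", detp_cols)
  beta <- as.matrix(x[, samples, drop = FALSE])
  detp <- as.matrix(x[, detp_cols, drop = FALSE])
  rownames(beta) <- rownames(detp) <- x$probe_id
  colnames(detp) <- samples
  list(beta = beta, detection_p = detp)
}

#' Write / read a probe manifest
#' @param manifest probe manifest.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) write_tsv(manifest, path)

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- read_tsv(path)
  man$chrom <- as.character(man$chrom)
  man$feature_group <- factor(man$feature_group, levels = FEATURE_LEVELS)
  man$cgi_relation <- factor(man$cgi_relation, levels = CGI_LEVELS)
  validate_manifest(man)
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' Export intervals as BED (0-based half-open)
#'
#' Internal interval coordinates are 1-based inclusive; BED start is
#' `start - 1`, BED end is `end`.
#'
#' @param intervals data.frame with chrom, start, end and either a `name`
#'   column or gene/feature_group/direction columns (joined with "|").
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name
  else if (all(c("gene", "feature_group", "direction") %in% names(intervals)))
    paste(intervals$gene, intervals$feature_group, intervals$direction,
          sep = "|")
  else if ("state" %in% names(intervals)) intervals$state
  else "."
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(intervals$end, scientific = FALSE,
                                 trim = TRUE),
                    name = name, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a plain gene list (one symbol per line)
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path input path.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
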