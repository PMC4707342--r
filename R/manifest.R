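# 450K-style probe manifest: coordinates, gene, feature group, CGI relation.

#' Gene feature group levels
#'
#' Mutually exclusive probe categories relative to a gene's transcription
#' start site (TSS): TSS200 (within 200 bp upstream), TSS1500 (200-1500 bp
#' upstream), 5'UTR/first exon, gene body, 3'UTR, and intergenic.  When a
#' probe could map to several features, a single category is assigned with
#' precedence TSS200 > TSS1500 > UTR5_1stExon > Body > UTR3 > Intergenic so
#' that category counts always partition the probe set.
#' @export
FEATURE_LEVELS <- c("TSS200", "TSS1500", "UTR5_1stExon", "Body", "UTR3",
                    "Intergenic")

#' CpG-island relation levels
#'
#' island = inside a CpG island; shore_shelf = within 4 kb of an island;
#' open_sea = beyond 4 kb of any island.
#' @export
CGI_LEVELS <- c("island", "shore_shelf", "open_sea")

# per-feature probe windows relative to the TSS (bp offsets, inclusive)
.feature_windows <- list(
  TSS200       = c(-200L, -1L),
  TSS1500      = c(-1500L, -201L),
  UTR5_1stExon = c(0L, 499L),
  Body         = c(500L, 15000L),
  UTR3         = c(15001L, 16000L),
  Intergenic   = c(30000L, 150000L)
)

#' Generate a synthetic methylation-array probe manifest
#'
#' Lays `n_genes` gene models on the autosomes (round-robin over
#' chromosomes, one 200 kb slot per gene) and places probes in each of the
#' six gene feature groups at coordinates consistent with the TSS: TSS200
#' probes fall within 200 bp upstream of the TSS, TSS1500 probes within
#' 200-1500 bp upstream, and so on.  Intergenic probes are placed in the gap
#' downstream of each gene model and carry no gene symbol.  Each probe gets
#' exactly one feature group and one CGI relation, so category counts
#' partition the probe set.
#'
#' @param n_genes number of gene models (>= 1).
#' @param probes_per_feature named integer vector of probes per feature
#'   group per gene slot; names must be `FEATURE_LEVELS`, all counts > 0.
#' @param cgi_fraction probability that a probe lies in a CpG island; the
#'   same fraction of the remainder is assigned shore_shelf, the rest is
#'   open sea.  0 gives an all-open-sea manifest.
#' @param seed integer seed; identical seeds give identical manifests.
#' @param n_chrom number of autosomes used (default 22).
#' @param gene_spacing bp between successive gene slots on a chromosome.
#' @return a `probe_manifest` data.frame: probe_id, chrom, pos (1-based),
#'   gene (NA for intergenic probes), feature_group, cgi_relation.
#' @export
make_manifest <- function(n_genes,
                          probes_per_feature = c(TSS200 = 2L, TSS1500 = 2L,
                                                 UTR5_1stExon = 2L, Body = 4L,
                                                 UTR3 = 1L, Intergenic = 3L),
                          cgi_fraction = 0.3,
                          seed = 1L,
                          n_chrom = 22L,
                          gene_spacing = 2e5) {
  if (length(n_genes) != 1L || !is.finite(n_genes) || n_genes < 1)
    stop_invalid("n_genes must be >= 1")
  if (is.null(names(probes_per_feature)) ||
      !setequal(names(probes_per_feature), FEATURE_LEVELS))
    stop_invalid("probes_per_feature must be named with all feature groups: ",
                 paste(FEATURE_LEVELS, collapse = ", "))
  probes_per_feature <- probes_per_feature[FEATURE_LEVELS]
  if (any(!is.finite(probes_per_feature)) || any(probes_per_feature <= 0))
    stop_invalid("probes_per_feature counts must be positive")
  if (cgi_fraction < 0 || cgi_fraction > 1)
    stop_invalid("cgi_fraction must be in [0, 1]")
  stopifnot(n_chrom >= 1L, n_chrom <= 22L, gene_spacing >= 2e5)

  n_genes <- as.integer(n_genes)
  ppf <- as.integer(probes_per_feature)
  names(ppf) <- FEATURE_LEVELS

  set.seed(derive_seed(seed, 11L))
  gene <- sprintf("GENE%04d", seq_len(n_genes))
  chrom <- as.character(((seq_len(n_genes) - 1L) %% n_chrom) + 1L)
  slot <- (seq_len(n_genes) - 1L) %/% n_chrom
  tss <- 100000L + slot * as.integer(gene_spacing)

  per_gene <- sum(ppf)
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    pos <- integer(0); feat <- character(0)
    for (f in FEATURE_LEVELS) {
      w <- .feature_windows[[f]]
      k <- ppf[[f]]
      pos <- c(pos, tss[i] + sort(sample(seq.int(w[1], w[2]), k)))
      feat <- c(feat, rep(f, k))
    }
    rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos,
      gene = ifelse(feat == "Intergenic", NA_character_, gene[i]),
      feature_group = feat, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  man$probe_id <- sprintf("cg%08d", seq_len(nrow(man)))

  u <- stats::runif(nrow(man))
  cgi <- ifelse(u < cgi_fraction, "island",
                ifelse(stats::runif(nrow(man)) < cgi_fraction,
                       "shore_shelf", "open_sea"))
  man$cgi_relation <- cgi

  man$feature_group <- factor(man$feature_group, levels = FEATURE_LEVELS)
  man$cgi_relation <- factor(man$cgi_relation, levels = CGI_LEVELS)
  ord <- order(as.integer(man$chrom), man$pos)
  man <- man[ord, c("probe_id", "chrom", "pos", "gene", "feature_group",
                    "cgi_relation")]
  rownames(man) <- NULL
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' Validate a probe manifest
#' @param manifest a data.frame with the `probe_manifest` columns.
#' @return the manifest, invisibly, after checks.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "gene", "feature_group", "cgi_relation")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop_invalid("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop_invalid("duplicated probe_id in manifest")
  if (!all(as.character(manifest$feature_group) %in% FEATURE_LEVELS))
    stop_invalid("unknown feature_group in manifest")
  if (!all(as.character(manifest$cgi_relation) %in% CGI_LEVELS))
    stop_invalid("unknown cgi_relation in manifest")
  invisible(manifest)
}
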