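# 450K-style differential methylation: beta computation, QC, group
# delta-beta with hyper/hypo classification, tabulation by gene feature
# and CGI relation, >= 2-probe region binning with BED export, two-sided
# beta marker selection with promoter refinement, and gene-set overlap.

#' Compute the methylation beta value
#'
#' `beta = M / (U + M + offset)` with the standard offset of 100, so beta
#' lies in \[0, 1) and is 0 when both intensities are 0.
#'
#' @param M methylated-allele intensity (>= 0; vector or matrix).
#' @param U unmethylated-allele intensity (>= 0; same shape).
#' @param offset stabilizing offset (default 100).
#' @return beta values, same shape as the inputs; NA propagates.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop_invalid("intensities must be non-negative")
  M / (U + M + offset)
}

#' Quality-control filter on detection P and blank betas
#'
#' A probe is removed when, in any sample, its detection P value exceeds
#' `p_t` (or is missing) or its beta is blank.  One genome-wide surviving
#' probe set is therefore shared by all downstream analyses.
#'
#' @param beta probe x sample beta matrix (NA = blank).
#' @param detection_p probe x sample detection P matrix.
#' @param p_t detection P threshold (default 0.05).
#' @return list: `beta`, `detection_p` (filtered), `removed` (probe ids),
#'   `n_kept`.
#' @export
qc_filter <- function(beta, detection_p, p_t = 0.05) {
  beta <- as.matrix(beta); detection_p <- as.matrix(detection_p)
  stopifnot(identical(dim(beta), dim(detection_p)))
  bad <- rowSums(is.na(beta) | is.na(detection_p) | detection_p > p_t) > 0L
  list(beta = beta[!bad, , drop = FALSE],
       detection_p = detection_p[!bad, , drop = FALSE],
       removed = rownames(beta)[bad] %||% which(bad),
       n_kept = sum(!bad))
}

#' Group-mean delta-beta with hyper/hypo classification
#'
#' `delta_beta = mean(beta in group_a) - mean(beta in group_b)` per probe;
#' a probe is hypermethylated iff `delta_beta > threshold` and
#' hypomethylated iff `delta_beta < -threshold`, both strict (a probe at
#' exactly the threshold is unclassified).
#'
#' @param beta probe x sample beta matrix (QC-passed; no NAs).
#' @param design a [group_design()].
#' @param group_a,group_b compared groups (a minus b); both non-empty.
#' @param threshold delta-beta threshold (default 0.2).
#' @return data.frame: probe_id, delta_beta, status
#'   ("hyper"/"hypo"/"none").
#' @export
group_delta_beta <- function(beta, design, group_a, group_b,
                             threshold = 0.2) {
  beta <- as.matrix(beta)
  check_matrix_design(beta, design)
  grp <- design$group[match(colnames(beta), design$sample_id)]
  a <- grp == group_a; b <- grp == group_b
  if (!any(a) || !any(b)) stop_invalid("both groups must be non-empty")
  d <- rowMeans(beta[, a, drop = FALSE]) - rowMeans(beta[, b, drop = FALSE])
  status <- rep("none", length(d))
  status[d > threshold] <- "hyper"
  status[d < -threshold] <- "hypo"
  data.frame(probe_id = rownames(beta) %||% as.character(seq_along(d)),
             delta_beta = unname(d), status = status,
             stringsAsFactors = FALSE)
}

#' Tabulate differential-methylation calls by feature group and CGI relation
#'
#' Counts and percentages of hyper- and hypomethylated probes per gene
#' feature group and per CGI relation.  Percentages are relative to the
#' number of (QC-passed) probes in each category; because every probe has
#' exactly one feature group and one CGI relation, category counts sum to
#' the grand total in both tables (a Total row is appended).
#'
#' @param calls [group_delta_beta()] output covering the QC-passed probe
#'   universe (status "none" rows included — they define the
#'   denominators).
#' @param manifest probe manifest covering every call.
#' @return list of two data.frames, `feature` and `cgi`, with columns
#'   category, n_probes, n_hyper, pct_hyper, n_hypo, pct_hypo.
#' @export
tabulate_by_feature <- function(calls, manifest) {
  validate_manifest(manifest)
  idx <- match(calls$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop_invalid("probes missing from manifest: ",
                 paste(utils::head(calls$probe_id[is.na(idx)], 5L),
                       collapse = ", "))
  one_table <- function(cat_levels, cat_values) {
    cat_values <- factor(as.character(cat_values), levels = cat_levels)
    tot <- table(cat_values)
    hyper <- table(cat_values[calls$status == "hyper"])
    hypo <- table(cat_values[calls$status == "hypo"])
    out <- data.frame(category = cat_levels,
                      n_probes = as.integer(tot),
                      n_hyper = as.integer(hyper),
                      pct_hyper = 100 * as.integer(hyper) / pmax(as.integer(tot), 1L),
                      n_hypo = as.integer(hypo),
                      pct_hypo = 100 * as.integer(hypo) / pmax(as.integer(tot), 1L),
                      stringsAsFactors = FALSE)
    total <- data.frame(category = "Total",
                        n_probes = sum(out$n_probes),
                        n_hyper = sum(out$n_hyper),
                        pct_hyper = 100 * sum(out$n_hyper) / max(sum(out$n_probes), 1L),
                        n_hypo = sum(out$n_hypo),
                        pct_hypo = 100 * sum(out$n_hypo) / max(sum(out$n_probes), 1L),
                        stringsAsFactors = FALSE)
    rbind(out, total)
  }
  list(feature = one_table(FEATURE_LEVELS, manifest$feature_group[idx]),
       cgi = one_table(CGI_LEVELS, manifest$cgi_relation[idx]))
}

#' Bin classified probes into differentially methylated regions
#'
#' Probes that individually pass the delta-beta threshold in the same
#' direction and fall in the same gene feature group of the same gene are
#' merged into one region; groups with fewer than `min_probes` probes (or
#' without a gene) yield no region.  The region span runs from the first
#' to the last member probe position.
#'
#' @param calls [group_delta_beta()] output.
#' @param manifest probe manifest.
#' @param direction "hyper" or "hypo".
#' @param min_probes minimum probes per region (default 2).
#' @return data.frame: gene, feature_group, chrom, start, end, n_probes,
#'   direction.
#' @export
bin_regions <- function(calls, manifest, direction = c("hyper", "hypo"),
                        min_probes = 2L) {
  direction <- match.arg(direction)
  validate_manifest(manifest)
  sel <- calls[calls$status == direction, , drop = FALSE]
  idx <- match(sel$probe_id, manifest$probe_id)
  if (anyNA(idx)) stop_invalid("calls contain probes missing from manifest")
  man <- manifest[idx, , drop = FALSE]
  keep <- !is.na(man$gene)
  man <- man[keep, , drop = FALSE]
  if (!nrow(man))
    return(data.frame(gene = character(0), feature_group = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  key <- paste(man$gene, man$feature_group, sep = "\r")
  pieces <- split(seq_len(nrow(man)), key)
  pieces <- pieces[vapply(pieces, length, integer(1)) >= min_probes]
  out <- do.call(rbind, lapply(pieces, function(ii) {
    data.frame(gene = man$gene[ii[1L]],
               feature_group = as.character(man$feature_group[ii[1L]]),
               chrom = man$chrom[ii[1L]],
               start = min(man$pos[ii]), end = max(man$pos[ii]),
               n_probes = length(ii), direction = direction,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(gene = character(0), feature_group = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$feature_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided beta-value marker selection between two groups
#'
#' A probe is a candidate marker iff every sample of one group has
#' `beta > hi` and every sample of the other group has `beta < lo`, both
#' strict.  Direction records which group is the methylated one.
#'
#' @param beta probe x sample beta matrix.
#' @param design a [group_design()].
#' @param group_a,group_b the two compared groups (defaults LMS and LM).
#' @param hi,lo beta thresholds (defaults 0.6 and 0.1).
#' @return data.frame: probe_id, direction ("hyper_in_<A>" or
#'   "hyper_in_<B>").
#' @export
select_methylation_markers <- function(beta, design,
                                       group_a = "LMS", group_b = "LM",
                                       hi = 0.6, lo = 0.1) {
  beta <- as.matrix(beta)
  check_matrix_design(beta, design)
  grp <- design$group[match(colnames(beta), design$sample_id)]
  a <- grp == group_a; b <- grp == group_b
  if (!any(a) || !any(b)) stop_invalid("both groups must be non-empty")
  hi_a <- rowSums(beta[, a, drop = FALSE] > hi) == sum(a)
  lo_a <- rowSums(beta[, a, drop = FALSE] < lo) == sum(a)
  hi_b <- rowSums(beta[, b, drop = FALSE] > hi) == sum(b)
  lo_b <- rowSums(beta[, b, drop = FALSE] < lo) == sum(b)
  sel_a <- hi_a & lo_b
  sel_b <- hi_b & lo_a
  data.frame(
    probe_id = c(rownames(beta)[sel_a], rownames(beta)[sel_b]),
    direction = c(rep(paste0("hyper_in_", group_a), sum(sel_a)),
                  rep(paste0("hyper_in_", group_b), sum(sel_b))),
    stringsAsFactors = FALSE)
}

#' Refine beta markers to promoter genes
#'
#' Keeps genes with at least `min_probes` marker probes mapped to the
#' promoter feature groups (TSS1500/TSS200).
#'
#' @param markers [select_methylation_markers()] output.
#' @param manifest probe manifest.
#' @param min_probes minimum promoter marker probes per gene (default 2).
#' @return data.frame: gene, n_probes, direction.
#' @export
promoter_refine <- function(markers, manifest, min_probes = 2L) {
  validate_manifest(manifest)
  idx <- match(markers$probe_id, manifest$probe_id)
  if (anyNA(idx)) stop_invalid("markers contain probes missing from manifest")
  man <- manifest[idx, , drop = FALSE]
  keep <- !is.na(man$gene) &
    as.character(man$feature_group) %in% c("TSS1500", "TSS200")
  man <- man[keep, , drop = FALSE]
  dir <- markers$direction[keep]
  if (!nrow(man))
    return(data.frame(gene = character(0), n_probes = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  key <- paste(man$gene, dir, sep = "\r")
  pieces <- split(seq_len(nrow(man)), key)
  pieces <- pieces[vapply(pieces, length, integer(1)) >= min_probes]
  out <- do.call(rbind, lapply(pieces, function(ii)
    data.frame(gene = man$gene[ii[1L]], n_probes = length(ii),
               direction = dir[ii[1L]], stringsAsFactors = FALSE)))
  if (is.null(out))
    return(data.frame(gene = character(0), n_probes = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Overlap of differentially methylated genes with a reference gene set
#'
#' @param dm_genes character vector of genes (e.g. hypermethylated genes).
#' @param reference_set character vector (e.g. polycomb-target genes);
#'   must be non-empty.
#' @return list(count, fraction): intersection size and its fraction of
#'   the reference set.
#' @export
geneset_overlap <- function(dm_genes, reference_set) {
  reference_set <- unique(reference_set)
  if (!length(reference_set)) stop_invalid("reference set is empty")
  count <- length(intersect(unique(dm_genes), reference_set))
  list(count = count, fraction = count / length(reference_set))
}

#' Per-sample beta five-number summaries and group medians
#'
#' @param beta probe x sample beta matrix with at least one probe.
#' @param design a [group_design()].
#' @return list: `samples` (sample_id, group, min, q1, median, q3, max)
#'   and `group_medians` (named vector of median of the sample medians per
#'   group).
#' @export
global_stats <- function(beta, design) {
  beta <- as.matrix(beta)
  if (nrow(beta) == 0L) stop_invalid("empty beta matrix")
  check_matrix_design(beta, design)
  grp <- design$group[match(colnames(beta), design$sample_id)]
  samples <- do.call(rbind, lapply(seq_len(ncol(beta)), function(ci) {
    x <- beta[, ci]
    if (all(is.na(x))) stop_invalid("sample ", colnames(beta)[ci],
                                    " has no beta values")
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    data.frame(sample_id = colnames(beta)[ci], group = as.character(grp[ci]),
               min = q[[1L]], q1 = q[[2L]], median = q[[3L]], q3 = q[[4L]],
               max = q[[5L]], stringsAsFactors = FALSE)
  }))
  gm <- tapply(samples$median, samples$group, stats::median)
  list(samples = samples, group_medians = gm[!is.na(gm)])
}
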