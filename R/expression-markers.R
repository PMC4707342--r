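# Expression analysis: quantile normalization, four-group one-way ANOVA
# with BH correction, fold-change and symbol-redundancy filters,
# flag/intensity tissue-specific marker selection, and per-sample DE
# counting against the normal-myometrium reference.

#' Quantile-normalize an intensity matrix
#'
#' After normalization every sample column shares one sorted-value
#' multiset: the per-rank mean of the input columns (ties share their rank
#' mean).  Within-sample rank order is preserved.  Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param mat probe x sample numeric matrix (>= 2 columns).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_invalid("need >= 2 samples")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Row-wise group means
#' @param mat probe x sample matrix.
#' @param design a [group_design()] covering the columns.
#' @return probe x group matrix (groups present in the design).
#' @export
group_means <- function(mat, design) {
  check_matrix_design(mat, design)
  grp <- design$group[match(colnames(mat), design$sample_id)]
  groups <- levels(droplevels(grp))
  out <- vapply(groups, function(g)
    rowMeans(mat[, grp == g, drop = FALSE]), numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), groups)
  out
}

#' Per-probe one-way ANOVA with Benjamini-Hochberg correction
#'
#' Computes, for every probe (row), the one-way ANOVA F statistic and
#' p-value across the design groups of the log2 matrix, then BH step-up
#' q-values over all tested probes.  A probe is selected iff `q < alpha`
#' (strict).  Degenerate rows with zero between- and within-group variance
#' get p = 1 by convention.
#'
#' @param log2_matrix probe x sample matrix of log2 intensities.
#' @param design a [group_design()]; at least two groups with at least two
#'   samples each.
#' @param alpha BH threshold (default 0.05).
#' @return data.frame: probe_id, f_stat, p, q, selected.
#' @export
anova_bh <- function(log2_matrix, design, alpha = 0.05) {
  mat <- as.matrix(log2_matrix)
  check_matrix_design(mat, design)
  grp <- droplevels(design$group[match(colnames(mat), design$sample_id)])
  sizes <- table(grp)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop_invalid("need >= 2 groups with >= 2 samples each")
  n <- ncol(mat); G <- length(sizes)
  grand <- rowMeans(mat)
  ss_tot <- rowSums((mat - grand)^2)
  gm <- group_means(mat, design)
  ssb <- as.vector((gm - grand)^2 %*% as.numeric(sizes[colnames(gm)]))
  ssw <- pmax(ss_tot - ssb, 0)
  df1 <- G - 1L; df2 <- n - G
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate: all values identical in every group
  degen <- ssb < 1e-24 & ssw < 1e-24
  f[degen] <- 0; p[degen] <- 1
  # perfectly separated groups with zero within variance
  exact <- ssw < 1e-24 & !degen
  f[exact] <- Inf; p[exact] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             f_stat = f, p = p, q = q, selected = q < alpha,
             stringsAsFactors = FALSE)
}

#' Fold-change filter over named group contrasts
#'
#' Keeps probes whose linear-scale fold change is `> fc` or `< 1/fc`
#' (strict) in at least one of the named contrasts; a probe at exactly the
#' threshold in every contrast is dropped.
#'
#' @param selection data.frame with a probe_id column (e.g. the selected
#'   rows of [anova_bh()]).
#' @param means probe x group matrix of linear-scale group means
#'   (see [group_means()]); all means must be > 0.
#' @param contrasts list of c(numerator_group, denominator_group);
#'   default LMS vs NM and LM vs NM.
#' @param fc fold-change threshold (default 2).
#' @return the filtered selection with one `fc_<A>_vs_<B>` column per
#'   contrast appended.
#' @export
fold_change_filter <- function(selection, means,
                               contrasts = list(c("LMS", "NM"),
                                                c("LM", "NM")),
                               fc = 2) {
  stopifnot(fc > 1)
  if (any(means <= 0)) stop_invalid("group means must be > 0")
  idx <- match(selection$probe_id, rownames(means))
  if (anyNA(idx)) stop_invalid("selection probes missing from means")
  keep <- rep(FALSE, nrow(selection))
  for (ct in contrasts) {
    r <- means[idx, ct[1L]] / means[idx, ct[2L]]
    selection[[paste0("fc_", ct[1L], "_vs_", ct[2L])]] <- r
    keep <- keep | r > fc | r < 1 / fc
  }
  selection[keep, , drop = FALSE]
}

#' Collapse a probe selection to unique gene symbols
#'
#' Probes without a gene symbol are removed; among probes sharing a
#' symbol, the one with the largest absolute log2 fold change over the
#' contrast columns survives (ties broken by lexicographically smaller
#' probe_id).
#'
#' @param selection output of [fold_change_filter()] (needs the `fc_*`
#'   columns).
#' @param annotation data.frame(probe_id, symbol).
#' @return gene-level selection with a `symbol` column.
#' @export
dedup_by_symbol <- function(selection, annotation) {
  sym <- annotation$symbol[match(selection$probe_id, annotation$probe_id)]
  keep <- !is.na(sym) & sym != ""
  selection <- selection[keep, , drop = FALSE]
  sym <- sym[keep]
  fc_cols <- grep("^fc_", names(selection), value = TRUE)
  if (!length(fc_cols)) stop_invalid("selection lacks fc_* contrast columns")
  score <- apply(abs(log2(as.matrix(selection[, fc_cols, drop = FALSE]))), 1L, max)
  ord <- order(sym, -score, selection$probe_id)
  selection <- selection[ord, , drop = FALSE]
  sym <- sym[ord]
  out <- selection[!duplicated(sym), , drop = FALSE]
  out$symbol <- sym[!duplicated(sym)]
  rownames(out) <- NULL
  out
}

#' Tissue-specific marker selection by flag and intensity
#'
#' A probe is specific to a class C of groups iff in every sample of every
#' group in C it is flagged present AND its normalized log2 intensity is
#' `> intensity_t`, and in every sample of every group outside C it is
#' flagged absent OR its intensity is `<= intensity_t`.  Probes on in all
#' groups, or clean in no class, are not markers.
#'
#' @param log2_matrix probe x sample normalized log2 intensities.
#' @param flags probe x sample character matrix ("present"/"absent").
#' @param design a [group_design()].
#' @param intensity_t log2 intensity threshold (default 6).
#' @return data.frame(probe_id, class) with classes like "LMS" or "NM/LM"
#'   (groups joined in canonical order).
#' @export
select_specific_markers <- function(log2_matrix, flags, design,
                                    intensity_t = 6) {
  mat <- as.matrix(log2_matrix)
  check_matrix_design(mat, design)
  stopifnot(identical(dim(mat), dim(flags)))
  grp <- design$group[match(colnames(mat), design$sample_id)]
  groups <- GROUP_LEVELS[GROUP_LEVELS %in% as.character(unique(grp))]
  on_g <- off_g <- matrix(FALSE, nrow(mat), length(groups),
                          dimnames = list(rownames(mat), groups))
  for (g in groups) {
    cols <- grp == g
    pres <- flags[, cols, drop = FALSE] == "present"
    hi <- mat[, cols, drop = FALSE] > intensity_t
    on_g[, g] <- rowSums(pres & hi) == sum(cols)
    off_g[, g] <- rowSums((!pres) | (!hi)) == sum(cols)
  }
  n_on <- rowSums(on_g)
  ok <- n_on >= 1L & n_on < length(groups) &
    rowSums(on_g | off_g) == length(groups)
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(probe_id = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  cls <- apply(on_g[idx, , drop = FALSE], 1L, function(z)
    paste(groups[z], collapse = "/"))
  data.frame(probe_id = rownames(mat)[idx], class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Per-sample DE counts against a reference group mean
#'
#' For every sample outside the reference group, counts probes whose
#' ratio to the reference-group mean exceeds `up_fc` (upregulated) or
#' falls below `down_fc` (downregulated), both strict.  Per non-reference
#' group, the "common" fraction is the size of the intersection of the
#' group's per-sample DE probe sets over the size of their union,
#' reported separately for up and down.
#'
#' @param mat probe x sample linear-scale normalized matrix.
#' @param design a [group_design()].
#' @param reference_group reference (default "NM"); must be non-empty.
#' @param up_fc,down_fc ratio thresholds (defaults 2.0 and 0.5).
#' @return list: `counts` (sample_id, group, n_up, n_down) and `common`
#'   (group, common_up, common_down, n_union_up, n_union_down).
#' @export
count_de_vs_reference <- function(mat, design, reference_group = "NM",
                                  up_fc = 2.0, down_fc = 0.5) {
  mat <- as.matrix(mat)
  check_matrix_design(mat, design)
  grp <- design$group[match(colnames(mat), design$sample_id)]
  ref_cols <- grp == reference_group
  if (!any(ref_cols)) stop_invalid("reference group is empty")
  ref_mean <- rowMeans(mat[, ref_cols, drop = FALSE])
  other <- which(!ref_cols)
  up_sets <- down_sets <- list()
  counts <- do.call(rbind, lapply(other, function(ci) {
    ratio <- mat[, ci] / ref_mean
    up <- ratio > up_fc; down <- ratio < down_fc
    sid <- colnames(mat)[ci]
    up_sets[[sid]] <<- rownames(mat)[up]
    down_sets[[sid]] <<- rownames(mat)[down]
    data.frame(sample_id = sid, group = as.character(grp[ci]),
               n_up = sum(up), n_down = sum(down), stringsAsFactors = FALSE)
  }))
  jacc <- function(sets) {
    if (!length(sets)) return(c(frac = NA_real_, union = 0))
    un <- Reduce(union, sets); int <- Reduce(intersect, sets)
    c(frac = if (length(un)) length(int) / length(un) else NA_real_,
      union = length(un))
  }
  common <- do.call(rbind, lapply(setdiff(unique(as.character(grp)),
                                          reference_group), function(g) {
    sids <- counts$sample_id[counts$group == g]
    ju <- jacc(up_sets[sids]); jd <- jacc(down_sets[sids])
    data.frame(group = g, common_up = ju[["frac"]], common_down = jd[["frac"]],
               n_union_up = ju[["union"]], n_union_down = jd[["union"]],
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, common = common)
}
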