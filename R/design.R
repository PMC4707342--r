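# Sample group design: which sample belongs to which tissue group.

#' Tissue group levels
#'
#' Canonical order of the sample groups: normal myometrium (NM), leiomyoma
#' (LM), leiomyosarcoma (LMS) and LMS-derived cell lines (CELL).
#' @export
GROUP_LEVELS <- c("NM", "LM", "LMS", "CELL")

#' Construct a sample group design
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector of group labels, one of
#'   `r paste(GROUP_LEVELS, collapse = ", ")`. Each of NM, LM and LMS must
#'   have at least one sample; CELL is optional.
#' @return a `group_design` data.frame with columns `sample_id` and `group`
#'   (factor with canonical levels).
#' @examples
#' group_design(c("NM1", "LM1", "LMS1"), c("NM", "LM", "LMS"))
#' @export
group_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop_invalid("sample_id and group must have equal length")
  if (anyDuplicated(sample_id))
    stop_invalid("duplicated sample_id")
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad))
    stop_invalid("unknown group(s): ", paste(bad, collapse = ", "))
  for (g in c("NM", "LM", "LMS"))
    if (!any(group == g))
      stop_invalid("design must contain at least one ", g, " sample")
  out <- data.frame(sample_id = sample_id,
                    group = factor(group, levels = GROUP_LEVELS),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_design", "data.frame")
  out
}

#' Default nine-sample tissue design (plus optional cell lines)
#'
#' Three samples each of normal myometrium, leiomyoma and leiomyosarcoma;
#' optionally LMS-derived cell lines as a fourth group.
#'
#' @param n_per_group samples per tissue group (default 3).
#' @param cell_lines number of cell-line samples appended (default 0).
#' @export
default_design <- function(n_per_group = 3L, cell_lines = 0L) {
  stopifnot(n_per_group >= 1L, cell_lines >= 0L)
  ids <- c(paste0("NM", seq_len(n_per_group)),
           paste0("LM", seq_len(n_per_group)),
           paste0("LMS", seq_len(n_per_group)))
  grp <- rep(c("NM", "LM", "LMS"), each = n_per_group)
  if (cell_lines > 0L) {
    ids <- c(ids, paste0("CELL", seq_len(cell_lines)))
    grp <- c(grp, rep("CELL", cell_lines))
  }
  group_design(ids, grp)
}

#' Samples of one group
#' @param design a `group_design`.
#' @param group group label.
#' @export
design_samples <- function(design, group) {
  design$sample_id[design$group == group]
}
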