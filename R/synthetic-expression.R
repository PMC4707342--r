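# Synthetic expression matrices: null probes share one intensity
# distribution; planted probes differ by a stated linear fold change;
# marker probes are switched on (present, high) only in their class.

#' Generate a synthetic expression matrix with planted effects
#'
#' Baseline per-probe log2 means are drawn N(`base_mean`, `base_sd`) and
#' per-cell values add N(0, `sample_sd`) noise.  `de_spec` plants
#' group-restricted fold changes: for every planted probe, samples of the
#' named group are shifted by `log2(fc)`.  `marker_spec` plants
#' class-specific on/off probes: samples in the class's groups get a high
#' "present" intensity (log2 ~ `marker_on`), all other samples get
#' near-background "absent" intensity (log2 ~ `background_mean`).  Flags
#' are present exactly when the raw log2 value exceeds `flag_threshold`, so
#' absent flags co-occur with near-background intensity.
#'
#' @param design a [group_design()].
#' @param n_probes number of probes.
#' @param de_spec data.frame(group, n, fc): plant `n` probes at linear fold
#'   change `fc` (> 0; > 1 up, < 1 down) in `group` relative to the rest.
#' @param marker_spec data.frame(class, n): plant `n` class-specific marker
#'   probes; `class` is a "/"-joined set of groups, e.g. "LMS" or "NM/LM".
#' @param sample_sd per-cell log2 noise (0 for a noiseless matrix).
#' @param base_mean,base_sd baseline log2 intensity distribution.
#' @param background_mean,background_sd near-background log2 intensity for
#'   switched-off marker probes.
#' @param marker_on,marker_on_sd log2 intensity of switched-on markers.
#' @param flag_threshold log2 level separating present from absent calls.
#' @param prop_symbol fraction of probes carrying a gene symbol.
#' @param gene_pool optional character vector of gene symbols to draw
#'   probe annotations from (e.g. the genes of a methylation manifest, so
#'   that expression and methylation share a gene universe); default is a
#'   synthetic pool of about one gene per 2.1 probes, the usual array
#'   probe-to-gene ratio.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return list: `intensity` (linear-scale probe x sample matrix), `flags`
#'   (character matrix "present"/"absent"), `annotation`
#'   (probe_id, symbol), `design`, and `truth` (`de` and `markers` tables).
#' @export
generate_expression <- function(design,
                                n_probes = 4000L,
                                de_spec = NULL,
                                marker_spec = NULL,
                                sample_sd = 0.25,
                                base_mean = 8, base_sd = 1,
                                background_mean = 4, background_sd = 0.4,
                                marker_on = 9, marker_on_sd = 0.3,
                                flag_threshold = 6,
                                prop_symbol = 0.9,
                                gene_pool = NULL,
                                seed = 1L) {
  stopifnot(inherits(design, "group_design"), n_probes >= 1L,
            sample_sd >= 0, base_sd >= 0, prop_symbol >= 0, prop_symbol <= 1)
  groups_present <- as.character(unique(design$group))
  if (!is.null(de_spec)) {
    stopifnot(all(c("group", "n", "fc") %in% names(de_spec)))
    if (!all(de_spec$group %in% groups_present))
      stop_invalid("de_spec references unknown group(s): ",
                   paste(setdiff(de_spec$group, groups_present), collapse = ", "))
    if (any(de_spec$fc <= 0)) stop_invalid("de_spec fold changes must be > 0")
  }
  if (!is.null(marker_spec)) {
    stopifnot(all(c("class", "n") %in% names(marker_spec)))
    cls_groups <- strsplit(as.character(marker_spec$class), "/", fixed = TRUE)
    for (gs in cls_groups)
      if (!all(gs %in% groups_present))
        stop_invalid("marker_spec class references unknown group(s): ",
                     paste(setdiff(gs, groups_present), collapse = ", "))
  }

  n_probes <- as.integer(n_probes)
  ns <- nrow(design)
  probe_id <- sprintf("EXPR%06d", seq_len(n_probes))

  set.seed(derive_seed(seed, 21L))
  mu <- stats::rnorm(n_probes, base_mean, base_sd)
  log2m <- matrix(mu, n_probes, ns) +
    matrix(stats::rnorm(n_probes * ns, 0, sample_sd), n_probes, ns)
  dimnames(log2m) <- list(probe_id, design$sample_id)

  # reserve distinct probes for DE effects then markers
  avail <- seq_len(n_probes)
  de_truth <- NULL
  if (!is.null(de_spec) && nrow(de_spec)) {
    n_need <- sum(de_spec$n)
    if (n_need > length(avail))
      stop_invalid("de_spec plants more probes than available")
    picks <- sample(avail, n_need)
    avail <- setdiff(avail, picks)
    off <- 0L
    de_truth <- do.call(rbind, lapply(seq_len(nrow(de_spec)), function(k) {
      idx <- picks[(off + 1L):(off + de_spec$n[k])]
      off <<- off + de_spec$n[k]
      cols <- design$group == de_spec$group[k]
      log2m[idx, cols] <<- log2m[idx, cols] + log2(de_spec$fc[k])
      data.frame(probe_id = probe_id[idx], group = de_spec$group[k],
                 fc = de_spec$fc[k], stringsAsFactors = FALSE)
    }))
  }

  marker_truth <- NULL
  if (!is.null(marker_spec) && nrow(marker_spec)) {
    n_need <- sum(marker_spec$n)
    if (n_need > length(avail))
      stop_invalid("marker_spec plants more probes than available")
    picks <- sample(avail, n_need)
    avail <- setdiff(avail, picks)
    off <- 0L
    marker_truth <- do.call(rbind, lapply(seq_len(nrow(marker_spec)), function(k) {
      idx <- picks[(off + 1L):(off + marker_spec$n[k])]
      off <<- off + marker_spec$n[k]
      gs <- strsplit(as.character(marker_spec$class[k]), "/", fixed = TRUE)[[1]]
      on_cols <- design$group %in% gs
      # noiseless request (sample_sd = 0) gives exactly reproducible on/off levels
      log2m[idx, on_cols] <<-
        matrix(stats::rnorm(length(idx) * sum(on_cols), marker_on,
                            marker_on_sd * (sample_sd > 0)),
               length(idx), sum(on_cols))
      log2m[idx, !on_cols] <<-
        matrix(stats::rnorm(length(idx) * sum(!on_cols), background_mean,
                            background_sd * (sample_sd > 0)),
               length(idx), sum(!on_cols))
      cls <- paste(GROUP_LEVELS[GROUP_LEVELS %in% gs], collapse = "/")
      data.frame(probe_id = probe_id[idx], class = cls,
                 stringsAsFactors = FALSE)
    }))
  }

  flags <- matrix(ifelse(log2m > flag_threshold, "present", "absent"),
                  n_probes, ns, dimnames = dimnames(log2m))

  if (is.null(gene_pool)) {
    n_genes <- max(1L, ceiling(n_probes / 2.1)) # ~2.1 probes/gene, array-like
    gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
  }
  symbols <- sample(gene_pool, n_probes, replace = TRUE)
  symbols[stats::runif(n_probes) > prop_symbol] <- NA_character_
  # planted marker/DE probes keep a symbol and get a unique one, so that
  # symbol dedup never collapses two planted probes into one
  planted_idx <- match(c(de_truth$probe_id, marker_truth$probe_id), probe_id)
  if (length(planted_idx))
    symbols[planted_idx] <- sprintf("PGENE%05d", seq_along(planted_idx))

  list(intensity = 2^log2m,
       flags = flags,
       annotation = data.frame(probe_id = probe_id, symbol = symbols,
                               stringsAsFactors = FALSE),
       design = design,
       truth = list(de = de_truth, markers = marker_truth))
}
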