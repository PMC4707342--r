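# End-to-end orchestration: configuration, the default synthetic
# scenario, per-stage execution with filter-funnel logging, clustering /
# PCA reporting and the methylation-by-expression scatter.

#' Hierarchical clustering of samples with design purity
#'
#' Complete-linkage agglomeration on Euclidean distances between sample
#' columns.  Purity at `k` clusters is the fraction of samples whose
#' cluster's majority group matches their own design group.
#'
#' @param mat feature x sample matrix (>= 2 samples).
#' @param design a [group_design()] covering the columns.
#' @param k number of clusters to cut at; default = number of distinct
#'   groups among the columns.
#' @param linkage,metric agglomeration method and distance (defaults
#'   "complete" and "euclidean").
#' @return list: `hclust`, `k`, `clusters` (named), `purity`.
#' @export
cluster_samples <- function(mat, design, k = NULL, linkage = "complete",
                            metric = "euclidean") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_invalid("need >= 2 samples")
  check_matrix_design(mat, design)
  grp <- design$group[match(colnames(mat), design$sample_id)]
  k <- k %||% length(unique(as.character(grp)))
  hc <- stats::hclust(stats::dist(t(mat), method = metric), method = linkage)
  cl <- stats::cutree(hc, k = k)
  purity <- sum(vapply(split(as.character(grp), cl), function(g)
    max(table(g)), numeric(1))) / ncol(mat)
  list(hclust = hc, k = k, clusters = cl, purity = purity)
}

#' PCA projection of samples
#'
#' Centered singular-value projection of the sample columns; variance
#' explained is reported per component and sums to at most 1.  A constant
#' matrix has zero variance and yields an empty projection.
#'
#' @param mat feature x sample matrix (>= 2 samples).
#' @param n_components components to return (default 3, capped at the
#'   matrix rank).
#' @return list: `scores` (sample x component), `var_explained`.
#' @export
pca_project <- function(mat, n_components = 3L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_invalid("need >= 2 samples")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-18)
    return(list(scores = matrix(0, ncol(mat), 0,
                                dimnames = list(colnames(mat), NULL)),
                var_explained = numeric(0)))
  nc <- min(n_components, sum(pc$sdev^2 / tot > 1e-12))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       var_explained = (pc$sdev^2 / tot)[seq_len(nc)])
}

#' Promoter methylation change versus expression change, per gene
#'
#' Pairs, for every shared gene, the mean delta-beta of its promoter
#' probes (TSS1500/TSS200) with its expression log2 fold change, and
#' reports their Spearman rank correlation.
#'
#' @param dm_calls [group_delta_beta()] output.
#' @param manifest probe manifest.
#' @param expr_fc data.frame(gene, log2fc).
#' @return list: `table` (gene, promoter_delta_beta, log2fc), `rho`, `p`.
#' @export
meth_expr_scatter <- function(dm_calls, manifest, expr_fc) {
  validate_manifest(manifest)
  idx <- match(dm_calls$probe_id, manifest$probe_id)
  keep <- !is.na(idx) &
    as.character(manifest$feature_group[idx]) %in% c("TSS1500", "TSS200") &
    !is.na(manifest$gene[idx])
  if (!any(keep)) stop_invalid("no promoter probes among the calls")
  gene <- manifest$gene[idx[keep]]
  db <- tapply(dm_calls$delta_beta[keep], gene, mean)
  tab <- data.frame(gene = names(db), promoter_delta_beta = as.numeric(db),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, expr_fc[, c("gene", "log2fc")], by = "gene")
  if (nrow(tab) == 0L)
    stop_invalid("no genes shared between methylation and expression")
  ct <- suppressWarnings(
    stats::cor.test(tab$promoter_delta_beta, tab$log2fc,
                    method = "spearman", exact = FALSE))
  list(table = tab, rho = unname(ct$estimate), p = ct$p.value)
}

#' Plant a burden profile of total fraction b on the synthetic probe grid
#'
#' Builds an aberration table covering (as nearly as the probe grid
#' allows) a fraction `b` of each chromosome's probed extent, cycling
#' through gain / loss / cnloh states across chromosomes.  A cnloh state
#' is only used when the planted span comfortably exceeds the detection
#' span floor (`min_cnloh_span`); otherwise that chromosome gets a gain.
#'
#' @param b target burden fraction in \[0, 1\].
#' @param n_chrom,probes_per_chrom,probe_spacing grid geometry, matching
#'   [generate_snp_array()].
#' @param mosaic_fraction mosaic fraction of every planted segment.
#' @param min_cnloh_span minimum span (bp) for planting a cnloh segment.
#' @return aberration data.frame (possibly 0 rows when b = 0).
#' @export
plant_burden_profile <- function(b, n_chrom = 4L, probes_per_chrom = 800L,
                                 probe_spacing = 10000L,
                                 mosaic_fraction = 1,
                                 min_cnloh_span = 3.3e6) {
  stopifnot(b >= 0, b <= 1)
  if (b == 0) return(NULL)
  states <- c("gain", "loss", "cnloh")
  rows <- lapply(seq_len(n_chrom), function(ch) {
    k <- round(b * (probes_per_chrom - 1L)) + 1L  # probes covered
    if (k < 2L) return(NULL)
    start <- 1
    end <- (k - 1) * probe_spacing + 1
    st <- states[(ch - 1L) %% 3L + 1L]
    if (st == "cnloh" && (end - start + 1) < min_cnloh_span) st <- "gain"
    data.frame(chrom = as.character(ch), start = start, end = end,
               state = st, mosaic_fraction = mosaic_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) validate_aberrations(out)
  out
}

#' Pipeline configuration
#'
#' Collects the sample design, stage thresholds (defaulting to the
#' standard values: delta-beta 0.2, fold change 2, BH q < 0.05, log2
#' intensity > 6, beta 0.6/0.1, 2-probe regions), generator settings for
#' synthetic mode or input paths for real mode, the seed and the output
#' directory.
#'
#' @param mode "synthetic" (generate all four modalities with planted
#'   truth) or "real" (read TSV inputs).
#' @param out_dir output directory for the report bundle.
#' @param seed top-level integer seed; all generator streams derive from
#'   it.
#' @param design a [group_design()]; default 3 NM + 3 LM + 3 LMS + 3
#'   cell lines.
#' @param thresholds named list overriding any of the stage defaults (see
#'   Details in the package vignette).
#' @param synthetic named list overriding generator settings (sizes,
#'   noise, planted magnitudes).
#' @param inputs named list of file paths for real mode: `snp_tracks`
#'   (named by sample), `expression`, `methylation`, `manifest`,
#'   `cobra_bands`, `cobra_controls`, optionally `geneset` (plain gene
#'   list for the overlap report).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            out_dir = tempfile("myomics_run_"),
                            seed = 1L,
                            design = default_design(3L, 3L),
                            thresholds = list(),
                            synthetic = list(),
                            inputs = list()) {
  mode <- match.arg(mode)
  th <- utils::modifyList(list(
    delta_beta = 0.2, fc = 2, alpha = 0.05, intensity_t = 6,
    beta_hi = 0.6, beta_lo = 0.1, min_probes = 2L,
    gain_t = 0.10, loss_t = -0.15,
    cnloh_min_run = 50L, cnloh_min_span = 3e6,
    baf_het_band = c(0.15, 0.85),
    detection_p = 0.05, up_fc = 2.0, down_fc = 0.5,
    seg_min_probes = 2L, seg_penalty = NULL), thresholds)
  stopifnot(th$delta_beta > 0, th$delta_beta < 1, th$fc > 1,
            th$alpha > 0, th$alpha < 1, th$beta_lo < th$beta_hi,
            th$loss_t < 0, th$gain_t > 0)
  sy <- utils::modifyList(list(
    n_genes = 300L, cgi_fraction = 0.3,
    n_probes_expr = 4000L, expr_sample_sd = 0.25,
    probes_per_chrom = 800L, probe_spacing = 10000L, n_chrom = 4L,
    lrr_noise_sd = 0.15, meth_noise_sd = 0.3, fail_rate = 0.005,
    burden = c(NM1 = 0, NM2 = 0, NM3 = 0,
               LM1 = 0.01, LM2 = 0.04, LM3 = 0.08,
               LMS1 = 0.70, LMS2 = 0.75, LMS3 = 0.80,
               CELL1 = 0.45, CELL2 = 0.50, CELL3 = 0.55),
    cobra_true = c(NM1 = 0.78, NM2 = 0.75, NM3 = 0.72,
                   LM1 = 0.74, LM2 = 0.70, LM3 = 0.68,
                   LMS1 = 0.45, LMS2 = 0.50, LMS3 = 0.55,
                   CELL1 = 0.70, CELL2 = 0.75, CELL3 = 0.65),
    cobra_slope = 0.9, cobra_intercept = 10, cobra_band_noise = 1.0),
    synthetic)
  if (mode == "real") {
    need <- c("snp_tracks", "expression", "methylation", "manifest",
              "cobra_bands", "cobra_controls")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop_invalid("real mode inputs missing: ", paste(miss, collapse = ", "))
    paths <- c(unlist(inputs$snp_tracks),
               inputs$expression, inputs$methylation, inputs$manifest,
               inputs$cobra_bands, inputs$cobra_controls, inputs$geneset)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop_invalid("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 design = design, thresholds = th, synthetic = sy,
                 inputs = inputs),
            class = "pipeline_config")
}

#' Generate the default synthetic study: all four modalities with truth
#'
#' The planted conditions emulate the study design the package targets:
#' three samples per tissue group plus cell lines; heavy chromosomal
#' burden in LMS (0.70-0.80) versus near none in LM (0.01-0.08); an
#' LMS-restricted expression programme (up- and downregulated probe sets,
#' 45 LMS-specific on/off markers, 4 NM, 1 LM, 4 NM/LM); LMS
#' hypomethylation graded by CGI relation (open sea >> shores/shelves >>
#' islands) with island-promoter hypermethylation at a polycomb-like gene
#' subset, plus milder symmetric LM changes; two promoter marker genes
#' planted at extreme betas (one methylated only in LMS, one only in LM);
#' and COBRA fractions lower in LMS, measured through a slope-0.9 /
#' intercept-10 distortion with a 0-100% control ladder.
#'
#' @param config a [pipeline_config()] in synthetic mode.
#' @return list: `manifest`, `snp`, `expr`, `meth`, `cobra`, `geneset`
#'   (the polycomb-like reference genes), `truth` (aggregated planted
#'   truth).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sy <- config$synthetic
  design <- config$design
  seed <- config$seed

  manifest <- make_manifest(sy$n_genes, cgi_fraction = sy$cgi_fraction,
                            seed = derive_seed(seed, 1L))
  genes <- unique(stats::na.omit(manifest$gene))

  # --- SNP arrays: per-sample planted burden ---------------------------
  burden <- sy$burden[names(sy$burden) %in% design$sample_id]
  aberr <- lapply(burden, plant_burden_profile,
                  n_chrom = sy$n_chrom,
                  probes_per_chrom = sy$probes_per_chrom,
                  probe_spacing = sy$probe_spacing)
  aberr <- aberr[!vapply(aberr, is.null, logical(1))]
  snp <- generate_snp_array(design, aberr,
                            probes_per_chrom = sy$probes_per_chrom,
                            probe_spacing = sy$probe_spacing,
                            n_chrom = sy$n_chrom,
                            noise_sd = sy$lrr_noise_sd,
                            seed = derive_seed(seed, 2L))

  # --- expression ------------------------------------------------------
  scale_n <- sy$n_probes_expr / 4000
  de_spec <- data.frame(
    group = c("LMS", "LMS", "LM", "LM", "CELL"),
    n = pmax(1L, as.integer(round(c(250L, 150L, 60L, 40L, 80L) * scale_n))),
    fc = c(4, 0.3, 3, 0.4, 3))
  de_spec <- de_spec[de_spec$group %in% as.character(unique(design$group)), ]
  marker_spec <- data.frame(
    class = c("LMS", "NM", "LM", "NM/LM"),
    n = c(45L, 4L, 1L, 4L))
  expr <- generate_expression(design, n_probes = sy$n_probes_expr,
                              de_spec = de_spec, marker_spec = marker_spec,
                              sample_sd = sy$expr_sample_sd,
                              gene_pool = genes,
                              seed = derive_seed(seed, 3L))

  # --- methylation -----------------------------------------------------
  pick <- function(cgi, frac, feature = NULL, exclude = character(0), s = 1L) {
    pool <- manifest[as.character(manifest$cgi_relation) %in% cgi, ]
    if (!is.null(feature))
      pool <- pool[as.character(pool$feature_group) %in% feature, ]
    n <- round(frac * nrow(pool))
    dm_spec_sample(manifest, group = "X", delta_beta = 0, n = n,
                   cgi_relation = cgi, feature_group = feature,
                   exclude = exclude, seed = derive_seed(seed, 60L + s))$probe_id
  }
  # two promoter marker genes at extreme betas, planted first so that no
  # other probe set can claim their promoter probes
  gs <- sort(genes)
  marker_gene_lms <- gs[1L]  # methylated only in LMS
  marker_gene_lm <- gs[2L]   # methylated only in LM
  prom_probes <- function(g) manifest$probe_id[
    !is.na(manifest$gene) & manifest$gene == g &
      as.character(manifest$feature_group) %in% c("TSS1500", "TSS200")]
  p_lms <- prom_probes(marker_gene_lms)
  p_lm <- prom_probes(marker_gene_lm)
  # polycomb-like reference set: 60 genes, a third with planted
  # island-promoter hypermethylation in LMS (promoters forced to a low
  # baseline so the planted +0.4 cannot clamp away)
  set.seed(derive_seed(seed, 65L))
  pcg_ref <- sort(sample(setdiff(gs, c(marker_gene_lms, marker_gene_lm)),
                         min(60L, length(gs) - 2L)))
  pcg_hyper <- pcg_ref[seq_len(min(20L, length(pcg_ref)))]
  pcg_probes <- manifest$probe_id[!is.na(manifest$gene) &
                                    manifest$gene %in% pcg_hyper &
                                    as.character(manifest$feature_group) %in%
                                    c("TSS1500", "TSS200")]
  reserved <- c(p_lms, p_lm, pcg_probes)
  # LMS: graded hypomethylation by CGI class + island hypermethylation
  hypo_sea <- pick("open_sea", 0.28, exclude = reserved, s = 1L)
  hypo_shore <- pick("shore_shelf", 0.17, exclude = reserved, s = 2L)
  hypo_island <- pick("island", 0.046, exclude = reserved, s = 3L)
  hyper_island <- pick("island", 0.045,
                       exclude = c(reserved, hypo_island), s = 4L)
  # LM: milder symmetric changes
  lm_hyper <- pick(c("island", "shore_shelf"), 0.03,
                   exclude = c(reserved, hypo_island, hypo_shore,
                               hyper_island), s = 5L)
  lm_hypo <- pick("open_sea", 0.02, exclude = c(reserved, hypo_sea), s = 6L)
  dm_spec <- rbind(
    data.frame(probe_id = hypo_sea, group = "LMS", delta_beta = -0.40),
    data.frame(probe_id = hypo_shore, group = "LMS", delta_beta = -0.40),
    data.frame(probe_id = hypo_island, group = "LMS", delta_beta = -0.35),
    data.frame(probe_id = hyper_island, group = "LMS", delta_beta = 0.40),
    data.frame(probe_id = pcg_probes, group = "LMS", delta_beta = 0.40),
    data.frame(probe_id = lm_hyper, group = "LM", delta_beta = 0.30),
    data.frame(probe_id = lm_hypo, group = "LM", delta_beta = -0.30),
    data.frame(probe_id = p_lms, group = "LMS", delta_beta = 0.80),
    data.frame(probe_id = p_lm, group = "LM", delta_beta = 0.80))
  dm_spec <- dm_spec[!duplicated(dm_spec$probe_id), , drop = FALSE]
  baseline_override <- c(
    stats::setNames(rep(0.03, length(p_lms) + length(p_lm)),
                    c(p_lms, p_lm)),
    stats::setNames(rep(0.15, length(pcg_probes)), pcg_probes))
  meth <- generate_methylation(design, manifest, dm_spec = dm_spec,
                               noise_sd = sy$meth_noise_sd,
                               fail_rate = sy$fail_rate,
                               baseline_override = baseline_override,
                               seed = derive_seed(seed, 4L))

  # --- COBRA -----------------------------------------------------------
  tf <- sy$cobra_true[names(sy$cobra_true) %in% design$sample_id]
  cobra <- generate_cobra(tf,
                          distortion = c(slope = sy$cobra_slope,
                                         intercept = sy$cobra_intercept),
                          band_noise = sy$cobra_band_noise,
                          seed = derive_seed(seed, 5L))

  list(manifest = manifest, snp = snp, expr = expr, meth = meth,
       cobra = cobra, geneset = pcg_ref,
       truth = list(snp = snp$truth, expr = expr$truth, meth = meth$truth,
                    cobra = cobra$truth,
                    pcg = list(reference = pcg_ref, planted = pcg_hyper),
                    promoter_markers = c(LMS = marker_gene_lms,
                                         LM = marker_gene_lm)))
}

#' Run the full pipeline and write the report bundle
#'
#' Stages run in dependency order: CNV burden per sample; expression
#' normalization, ANOVA/BH, fold-change and symbol filters, specific
#' markers and DE counts; methylation QC, delta-beta for LMS-vs-NM and
#' LM-vs-NM, feature/CGI tabulation, region binning with BED export,
#' beta-marker selection with promoter refinement, gene-set overlap and
#' global stats; COBRA quantification with standard-curve correction; and
#' clustering/PCA/scatter reporting.  Identical config + seed gives an
#' identical bundle.  Per-stage probe counts (the filter funnel) are
#' written to the run log together with a config echo.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list (see the vignette); files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  design <- config$design
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  if (config$mode == "synthetic") {
    sim <- simulate_scenario(config)
    manifest <- sim$manifest
    tracks <- sim$snp$tracks
    expr <- sim$expr
    beta <- sim$meth$beta; detp <- sim$meth$detection_p
    bands <- sim$cobra$bands; controls <- sim$cobra$controls
    geneset <- sim$geneset
    truth <- sim$truth
  } else {
    ip <- config$inputs
    manifest <- read_manifest(ip$manifest)
    tracks <- lapply(ip$snp_tracks, read_snp_track)
    expr <- read_expression(ip$expression)
    bm <- read_beta_matrix(ip$methylation)
    beta <- bm$beta; detp <- bm$detection_p
    cb <- read_tsv(ip$cobra_bands); bands <- cb
    controls <- read_tsv(ip$cobra_controls)
    geneset <- if (!is.null(ip$geneset)) read_gene_list(ip$geneset) else NULL
    truth <- NULL
  }
  funnel <- list()

  # --- CNV burden ------------------------------------------------------
  cnv <- lapply(names(tracks), function(sid)
    call_cnv_sample(tracks[[sid]], sample_id = sid,
                    penalty = th$seg_penalty, min_probes = th$seg_min_probes,
                    gain_t = th$gain_t, loss_t = th$loss_t,
                    min_run = th$cnloh_min_run,
                    baf_het_band = th$baf_het_band,
                    min_span = th$cnloh_min_span))
  names(cnv) <- names(tracks)
  burden <- do.call(rbind, lapply(cnv, `[[`, "burden"))
  write_tsv(burden, out("burden.tsv"))
  for (sid in names(cnv)) {
    seg <- rbind(cnv[[sid]]$segments, cnv[[sid]]$cnloh)
    seg <- seg[seg$state != "neutral", , drop = FALSE]
    write_bed(seg, out(paste0("segments_", sid, ".bed")))
  }

  # --- expression ------------------------------------------------------
  norm <- quantile_normalize(expr$intensity)
  log2m <- log2(norm)
  de <- anova_bh(log2m, design, alpha = th$alpha)
  funnel$expr_probes_total <- nrow(de)
  de_sel <- de[de$selected, , drop = FALSE]
  funnel$expr_anova_selected <- nrow(de_sel)
  gmeans <- group_means(norm, design)
  fc_sel <- fold_change_filter(de_sel, gmeans, fc = th$fc)
  funnel$expr_fc_selected <- nrow(fc_sel)
  de_genes <- dedup_by_symbol(fc_sel, expr$annotation)
  funnel$expr_symbol_deduplicated <- nrow(de_genes)
  markers <- select_specific_markers(log2m, expr$flags, design,
                                     intensity_t = th$intensity_t)
  markers$symbol <- expr$annotation$symbol[
    match(markers$probe_id, expr$annotation$probe_id)]
  de_counts <- count_de_vs_reference(norm, design, "NM",
                                     up_fc = th$up_fc, down_fc = th$down_fc)
  write_tsv(de_genes, out("de_genes.tsv"))
  write_tsv(markers, out("expression_markers.tsv"))
  write_tsv(de_counts$counts, out("de_counts.tsv"))
  write_tsv(de_counts$common, out("de_common.tsv"))
  write_gene_list(stats::na.omit(unique(de_genes$symbol)),
                  out("de_gene_list.txt"))

  # --- methylation -----------------------------------------------------
  qc <- qc_filter(beta, detp, p_t = th$detection_p)
  funnel$meth_probes_total <- nrow(beta)
  funnel$meth_probes_qc_passed <- qc$n_kept
  man_qc <- manifest[manifest$probe_id %in% rownames(qc$beta), , drop = FALSE]
  dm_lms <- group_delta_beta(qc$beta, design, "LMS", "NM", th$delta_beta)
  dm_lm <- group_delta_beta(qc$beta, design, "LM", "NM", th$delta_beta)
  funnel$meth_lms_hyper <- sum(dm_lms$status == "hyper")
  funnel$meth_lms_hypo <- sum(dm_lms$status == "hypo")
  tab_lms <- tabulate_by_feature(dm_lms, manifest)
  tab_lm <- tabulate_by_feature(dm_lm, manifest)
  write_tsv(dm_lms, out("dm_calls_LMSvsNM.tsv"))
  write_tsv(tab_lms$feature, out("dm_table_feature_LMSvsNM.tsv"))
  write_tsv(tab_lms$cgi, out("dm_table_cgi_LMSvsNM.tsv"))
  write_tsv(tab_lm$feature, out("dm_table_feature_LMvsNM.tsv"))
  write_tsv(tab_lm$cgi, out("dm_table_cgi_LMvsNM.tsv"))
  regions <- list(hyper = bin_regions(dm_lms, manifest, "hyper",
                                      th$min_probes),
                  hypo = bin_regions(dm_lms, manifest, "hypo",
                                     th$min_probes))
  write_bed(regions$hyper, out("regions_hyper_LMSvsNM.bed"))
  write_bed(regions$hypo, out("regions_hypo_LMSvsNM.bed"))
  meth_markers <- select_methylation_markers(qc$beta, design, "LMS", "LM",
                                             hi = th$beta_hi, lo = th$beta_lo)
  prom_genes <- promoter_refine(meth_markers, manifest, th$min_probes)
  write_tsv(meth_markers, out("methylation_markers.tsv"))
  write_tsv(prom_genes, out("methylation_marker_genes.tsv"))
  overlap <- NULL
  if (!is.null(geneset) && length(geneset)) {
    hyper_genes <- unique(regions$hyper$gene)
    overlap <- geneset_overlap(hyper_genes, geneset)
  }
  gstats <- global_stats(qc$beta, design)
  write_tsv(gstats$samples, out("beta_global_stats.tsv"))

  # --- COBRA -----------------------------------------------------------
  curve <- fit_standard_curve(controls$true_pct, controls$raw_pct)
  cobra_tab <- cobra_quantify(bands, curve)
  write_tsv(cobra_tab, out("cobra_index.tsv"))

  # --- reporting: clustering, PCA, scatter -----------------------------
  tissue <- design$sample_id[design$group != "CELL"]
  sel_log2 <- log2m[de_genes$probe_id, , drop = FALSE]
  clust_expr <- if (nrow(sel_log2) >= 2L)
    cluster_samples(sel_log2[, tissue, drop = FALSE], design, k = 3L)
  else NULL
  clust_beta <- cluster_samples(qc$beta[, tissue, drop = FALSE], design,
                                k = 3L)
  pca <- pca_project(log2m)
  fc_lms <- log2(gmeans[, "LMS"] / gmeans[, "NM"])
  sym <- expr$annotation$symbol[match(rownames(gmeans),
                                      expr$annotation$probe_id)]
  keep <- !is.na(sym)
  expr_fc <- data.frame(gene = sym[keep], log2fc = fc_lms[keep],
                        stringsAsFactors = FALSE)
  expr_fc <- stats::aggregate(log2fc ~ gene, expr_fc, mean)
  scatter <- tryCatch(meth_expr_scatter(dm_lms, manifest, expr_fc),
                      error = function(e) NULL)
  if (!is.null(scatter))
    write_tsv(scatter$table, out("meth_expr_scatter.tsv"))

  cfg_echo <- list(mode = config$mode, seed = config$seed,
                   thresholds = config$thresholds,
                   n_samples = nrow(design),
                   groups = as.list(table(design$group)))
  log <- list(config = cfg_echo, funnel = funnel,
              clustering = list(
                expr_purity = if (!is.null(clust_expr)) clust_expr$purity
                else NA,
                beta_purity = clust_beta$purity),
              cobra_r2 = curve$r2,
              scatter_rho = if (!is.null(scatter)) scatter$rho else NA)
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  bundle <- list(burden = burden, cnv = cnv,
                 expression = list(normalized = norm, log2 = log2m,
                                   anova = de, fc_selected = fc_sel,
                                   de_genes = de_genes, markers = markers,
                                   de_counts = de_counts),
                 methylation = list(qc = qc, dm_lms = dm_lms, dm_lm = dm_lm,
                                    tables_lms = tab_lms,
                                    tables_lm = tab_lm,
                                    regions = regions,
                                    markers = meth_markers,
                                    promoter_genes = prom_genes,
                                    overlap = overlap,
                                    global_stats = gstats),
                 cobra = list(curve = curve, index = cobra_tab),
                 reports = list(clust_expr = clust_expr,
                                clust_beta = clust_beta, pca = pca,
                                scatter = scatter),
                 funnel = funnel, truth = truth,
                 out_dir = config$out_dir)
  class(bundle) <- "report_bundle"
  bundle
}
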