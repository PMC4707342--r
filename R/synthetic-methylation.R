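# Synthetic 450K-style methylation data: methylated/unmethylated
# intensities plus detection P values, with planted group-wise delta-beta.

#' Generate synthetic methylation intensities with planted delta-beta
#'
#' Each probe gets a baseline beta drawn by CGI relation (islands low,
#' open sea high, shores/shelves intermediate — the canonical 450K
#' bimodality).  `dm_spec` plants group-restricted shifts: for samples of
#' the named group the target beta is `baseline + delta_beta` (clamped to
#' (0, 0.95]).  Per-cell noise is additive Gaussian on the logit of the
#' target beta, which keeps values inside (0, 1).  Methylated/unmethylated
#' intensities are reconstructed so that `compute_beta(M, U)` returns the
#' noisy beta exactly: `M = b * (S + offset)`, `U = S - M` at total
#' intensity `S`.  A small uniform fraction of cells gets a failing
#' detection P (> 0.05) and, optionally, blank betas, to exercise QC.
#'
#' @param design a [group_design()].
#' @param manifest a [make_manifest()] probe manifest.
#' @param dm_spec data.frame(probe_id, group, delta_beta) of planted shifts
#'   (|delta_beta| <= 1; probes must exist in the manifest).
#' @param noise_sd Gaussian sd on logit(beta) per cell (default 0.3).
#' @param fail_rate fraction of cells given detection P > 0.05
#'   (default 0.005).
#' @param blank_rate fraction of cells with blank (NA) beta.
#' @param total_intensity total M+U intensity per cell.
#' @param offset beta-value offset (100, the array convention).
#' @param baseline_override optional named numeric vector (by probe_id)
#'   forcing the baseline beta of specific probes (e.g. to plant promoter
#'   probes that are nearly unmethylated in every group except the one
#'   shifted by `dm_spec`).
#' @param seed integer seed.
#' @return list: `M`, `U`, `beta`, `detection_p` (probe x sample matrices),
#'   `design`, `manifest`, and `truth` (`dm` table plus per-probe baseline).
#' @export
generate_methylation <- function(design, manifest,
                                 dm_spec = NULL,
                                 noise_sd = 0.3,
                                 fail_rate = 0.005,
                                 blank_rate = 0,
                                 total_intensity = 4000,
                                 offset = 100,
                                 baseline_override = NULL,
                                 seed = 1L) {
  stopifnot(inherits(design, "group_design"), noise_sd >= 0,
            fail_rate >= 0, fail_rate <= 1, blank_rate >= 0, blank_rate <= 1,
            total_intensity > 10 * offset)
  validate_manifest(manifest)
  groups_present <- as.character(unique(design$group))
  if (!is.null(dm_spec) && nrow(dm_spec)) {
    stopifnot(all(c("probe_id", "group", "delta_beta") %in% names(dm_spec)))
    missing <- setdiff(dm_spec$probe_id, manifest$probe_id)
    if (length(missing))
      stop_invalid("dm_spec probes absent from manifest: ",
                   paste(utils::head(missing, 5L), collapse = ", "))
    if (!all(dm_spec$group %in% groups_present))
      stop_invalid("dm_spec references unknown group(s)")
    if (any(abs(dm_spec$delta_beta) > 1))
      stop_invalid("planted |delta_beta| must be <= 1")
  }

  np <- nrow(manifest); ns <- nrow(design)
  set.seed(derive_seed(seed, 31L))

  base <- numeric(np)
  cgi <- as.character(manifest$cgi_relation)
  base[cgi == "island"] <- stats::rbeta(sum(cgi == "island"), 2, 8)
  base[cgi == "shore_shelf"] <- stats::rbeta(sum(cgi == "shore_shelf"), 5, 5)
  base[cgi == "open_sea"] <- stats::rbeta(sum(cgi == "open_sea"), 8, 3)
  if (!is.null(baseline_override)) {
    ov <- match(names(baseline_override), manifest$probe_id)
    if (anyNA(ov))
      stop_invalid("baseline_override probes absent from manifest")
    base[ov] <- baseline_override
  }

  # per-cell target beta
  target <- matrix(base, np, ns,
                   dimnames = list(manifest$probe_id, design$sample_id))
  if (!is.null(dm_spec) && nrow(dm_spec)) {
    for (g in unique(dm_spec$group)) {
      rows <- match(dm_spec$probe_id[dm_spec$group == g], manifest$probe_id)
      cols <- design$group == g
      target[rows, cols] <- target[rows, cols] +
        dm_spec$delta_beta[dm_spec$group == g]
    }
  }
  bmax <- total_intensity / (total_intensity + offset) - 1e-6
  target <- clamp(target, 0.005, 0.95)

  b <- stats::plogis(stats::qlogis(target) +
                       matrix(stats::rnorm(np * ns, 0, noise_sd), np, ns))
  b <- clamp(b, 1e-4, bmax)

  M <- b * (total_intensity + offset)
  U <- total_intensity - M
  dimnames(M) <- dimnames(U) <- dimnames(target)

  detp <- matrix(stats::runif(np * ns, 0, 0.04), np, ns,
                 dimnames = dimnames(target))
  fail <- matrix(stats::runif(np * ns) < fail_rate, np, ns)
  detp[fail] <- stats::runif(sum(fail), 0.051, 1)

  beta <- compute_beta(M, U, offset = offset)
  if (blank_rate > 0) {
    blank <- matrix(stats::runif(np * ns) < blank_rate, np, ns)
    beta[blank] <- NA_real_
  }

  list(M = M, U = U, beta = beta, detection_p = detp,
       design = design, manifest = manifest,
       truth = list(dm = dm_spec, baseline = stats::setNames(base, manifest$probe_id)))
}

#' Sample a planted differential-methylation spec from a manifest
#'
#' Convenience builder: pick `n` probes from a manifest subset (by CGI
#' relation and/or feature group) and assign them one planted delta-beta in
#' one group.
#'
#' @param manifest a probe manifest.
#' @param group group carrying the shift.
#' @param delta_beta planted shift.
#' @param n number of probes.
#' @param cgi_relation,feature_group optional filters.
#' @param exclude probe_ids never picked (already planted elsewhere).
#' @param seed integer seed.
#' @export
dm_spec_sample <- function(manifest, group, delta_beta, n,
                           cgi_relation = NULL, feature_group = NULL,
                           exclude = character(0), seed = 1L) {
  pool <- manifest
  if (!is.null(cgi_relation))
    pool <- pool[as.character(pool$cgi_relation) %in% cgi_relation, ]
  if (!is.null(feature_group))
    pool <- pool[as.character(pool$feature_group) %in% feature_group, ]
  pool <- pool[!(pool$probe_id %in% exclude), ]
  if (nrow(pool) < n)
    stop_invalid("not enough probes in the requested manifest subset (",
                 nrow(pool), " < ", n, ")")
  set.seed(derive_seed(seed, 41L))
  data.frame(probe_id = sample(pool$probe_id, n), group = group,
             delta_beta = delta_beta, stringsAsFactors = FALSE)
}
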