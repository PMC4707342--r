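# Synthetic SNP-array tracks: piecewise-constant LRR/BAF with planted
# gain / loss / copy-neutral-LOH segments at given mosaic fractions.

#' Build an aberration specification table
#'
#' @param chrom,start,end interval (1-based inclusive) on one chromosome.
#' @param state one of "gain", "loss", "cnloh".
#' @param mosaic_fraction fraction of cells carrying the aberration, in
#'   (0, 1]; attenuates the LRR shift and BAF split.
#' @return data.frame usable inside the per-sample aberration list of
#'   [generate_snp_array()].
#' @export
aberration_spec <- function(chrom, start, end, state, mosaic_fraction = 1) {
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    state = as.character(state),
                    mosaic_fraction = as.numeric(mosaic_fraction),
                    stringsAsFactors = FALSE)
  validate_aberrations(out)
  out
}

#' @noRd
validate_aberrations <- function(ab) {
  if (is.null(ab) || nrow(ab) == 0L) return(invisible(ab))
  need <- c("chrom", "start", "end", "state", "mosaic_fraction")
  miss <- setdiff(need, names(ab))
  if (length(miss))
    stop_invalid("aberration spec lacks columns: ", paste(miss, collapse = ", "))
  if (!all(ab$state %in% c("gain", "loss", "cnloh")))
    stop_invalid("aberration state must be gain, loss or cnloh")
  if (any(ab$start > ab$end))
    stop_invalid("aberration start > end")
  if (any(ab$mosaic_fraction <= 0 | ab$mosaic_fraction > 1))
    stop_invalid("mosaic_fraction must be in (0, 1]")
  # overlap check within chromosome
  for (ch in unique(ab$chrom)) {
    x <- ab[ab$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start[-1L] <= x$end[-nrow(x)]))
      stop_invalid("overlapping aberrations on chromosome ", ch)
  }
  invisible(ab)
}

# heterozygous BAF half-split for a single-copy change at mosaic fraction f
baf_split_delta <- function(f) f / (4 - 2 * f)

#' Generate synthetic SNP-array tracks with planted aberrations
#'
#' Probes are laid on a regular grid of `probes_per_chrom` probes spaced
#' `probe_spacing` bp on `n_chrom` autosomes.  Genotypes are drawn
#' Hardy-Weinberg with allele frequency 0.5 (AA:AB:BB = 1:2:1).  Baseline
#' LRR is 0 with additive Gaussian noise; baseline BAF is 0 / 0.5 / 1 by
#' genotype with (smaller) additive noise, clamped to \[0, 1\].  Inside a
#' planted aberration at mosaic fraction f:
#' * gain: LRR shifts by `+gain_shift * f`; heterozygous BAF splits to
#'   `0.5 +/- f/(4 - 2f)`;
#' * loss: LRR shifts by `-loss_shift * f`; heterozygous BAF splits the
#'   same way;
#' * cnloh: LRR stays 0; a fraction f of heterozygous probes is re-drawn
#'   from near 0 / near 1.
#'
#' @param design a [group_design()]; one track per sample.
#' @param aberrations named list (by sample_id) of aberration tables (see
#'   [aberration_spec()]); samples absent from the list get a clean genome.
#' @param probes_per_chrom probes per chromosome.
#' @param probe_spacing bp between adjacent probes.
#' @param n_chrom number of autosomes simulated.
#' @param noise_sd additive Gaussian noise on LRR (>= 0).
#' @param baf_noise_sd additive Gaussian noise on BAF; default `noise_sd/5`
#'   so that a noiseless request is noiseless in both metrics.
#' @param gain_shift,loss_shift full-clonality LRR shift magnitudes
#'   (defaults +0.40 and 0.55, near typical genotyping-array single-copy
#'   shifts).
#' @param seed integer seed.
#' @return list with `tracks` (named list of per-sample data.frames:
#'   probe_id, chrom, pos, lrr, baf, genotype) and `truth` (the validated
#'   aberration list plus the planted per-sample burden fractions on the
#'   probed extent).
#' @export
generate_snp_array <- function(design,
                               aberrations = list(),
                               probes_per_chrom = 800L,
                               probe_spacing = 10000L,
                               n_chrom = 4L,
                               noise_sd = 0.15,
                               baf_noise_sd = NULL,
                               gain_shift = 0.40,
                               loss_shift = 0.55,
                               seed = 1L) {
  stopifnot(inherits(design, "group_design"), noise_sd >= 0,
            probes_per_chrom >= 2L, probe_spacing >= 1, n_chrom >= 1L,
            gain_shift > 0, loss_shift > 0)
  baf_noise_sd <- baf_noise_sd %||% (noise_sd / 5)
  stopifnot(baf_noise_sd >= 0)
  bad <- setdiff(names(aberrations), design$sample_id)
  if (length(bad))
    stop_invalid("aberrations given for unknown samples: ",
                 paste(bad, collapse = ", "))
  for (ab in aberrations) validate_aberrations(ab)

  pos1 <- (seq_len(probes_per_chrom) - 1L) * as.integer(probe_spacing) + 1L
  grid <- data.frame(
    chrom = rep(as.character(seq_len(n_chrom)), each = probes_per_chrom),
    pos = rep(pos1, n_chrom), stringsAsFactors = FALSE)
  grid$probe_id <- sprintf("snp%07d", seq_len(nrow(grid)))
  np <- nrow(grid)

  tracks <- vector("list", nrow(design))
  names(tracks) <- design$sample_id
  for (si in seq_len(nrow(design))) {
    sid <- design$sample_id[si]
    set.seed(derive_seed(seed, 100L + si))
    geno <- sample(c("AA", "AB", "BB"), np, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
    lrr <- stats::rnorm(np, 0, noise_sd)
    baf0 <- c(AA = 0, AB = 0.5, BB = 1)[geno]
    baf <- baf0 + stats::rnorm(np, 0, baf_noise_sd)

    ab <- aberrations[[sid]]
    if (!is.null(ab) && nrow(ab)) {
      for (k in seq_len(nrow(ab))) {
        idx <- which(grid$chrom == ab$chrom[k] &
                       grid$pos >= ab$start[k] & grid$pos <= ab$end[k])
        if (!length(idx)) next
        f <- ab$mosaic_fraction[k]
        het <- idx[geno[idx] == "AB"]
        if (ab$state[k] == "gain") {
          lrr[idx] <- lrr[idx] + gain_shift * f
          d <- baf_split_delta(f)
          sgn <- sample(c(-1, 1), length(het), replace = TRUE)
          baf[het] <- 0.5 + sgn * d + stats::rnorm(length(het), 0, baf_noise_sd)
        } else if (ab$state[k] == "loss") {
          lrr[idx] <- lrr[idx] - loss_shift * f
          d <- baf_split_delta(f)
          sgn <- sample(c(-1, 1), length(het), replace = TRUE)
          baf[het] <- 0.5 + sgn * d + stats::rnorm(length(het), 0, baf_noise_sd)
        } else { # cnloh: LRR untouched, fraction f of hets pushed to 0/1
          flip <- het[stats::runif(length(het)) < f]
          hom <- sample(c(0, 1), length(flip), replace = TRUE)
          baf[flip] <- hom + stats::rnorm(length(flip), 0, baf_noise_sd)
        }
      }
    }
    baf <- clamp(baf, 0, 1)
    tracks[[si]] <- data.frame(probe_id = grid$probe_id, chrom = grid$chrom,
                               pos = grid$pos, lrr = lrr, baf = baf,
                               genotype = geno, stringsAsFactors = FALSE)
  }

  basis <- data.frame(chrom = as.character(seq_len(n_chrom)),
                      start = pos1[1L], end = pos1[length(pos1)],
                      stringsAsFactors = FALSE)
  basis_bp <- sum(basis$end - basis$start + 1)
  planted <- do.call(rbind, lapply(design$sample_id, function(sid) {
    ab <- aberrations[[sid]]
    gl <- cn <- 0
    if (!is.null(ab) && nrow(ab)) {
      ov <- pmin(ab$end, basis$end[match(ab$chrom, basis$chrom)]) -
        pmax(ab$start, basis$start[match(ab$chrom, basis$chrom)]) + 1
      ov <- pmax(ov, 0)
      gl <- sum(ov[ab$state %in% c("gain", "loss")])
      cn <- sum(ov[ab$state == "cnloh"])
    }
    data.frame(sample_id = sid, frac_gain_loss = gl / basis_bp,
               frac_cnloh = cn / basis_bp,
               frac_total = (gl + cn) / basis_bp, stringsAsFactors = FALSE)
  }))

  list(tracks = tracks,
       truth = list(aberrations = aberrations, burden = planted,
                    basis = basis))
}
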