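# Chromosomal-abnormality burden from SNP-array LRR/BAF tracks:
# penalized least-squares segmentation of LRR, gain/loss state calling,
# copy-neutral-LOH detection from BAF runs, and the per-sample burden
# ratio (fraction of the probed autosomal genome in an aberrant state).

#' Segment an LRR track by exact penalized least squares
#'
#' Fits, independently per chromosome, the piecewise-constant signal
#' minimizing `RSS + penalty * (number of breakpoints)` subject to every
#' segment containing at least `min_probes` probes.  The optimum is found
#' exactly by an O(n^2) optimal-partitioning dynamic program, so the result
#' provably equals an exhaustive search over breakpoint placements (the
#' same piecewise-constant model class as sparse-Bayesian CNV callers, but
#' reproducible and oracle-checkable).
#'
#' The default penalty is `10 * sigma^2`, with `sigma` estimated robustly
#' from the median absolute successive difference of the LRR
#' (`median(|diff|) / (0.6745 * sqrt(2))`), so that a breakpoint must
#' explain clearly more variance than noise.
#'
#' @param track data.frame with columns probe_id, chrom, pos, lrr (and
#'   optionally baf, genotype), sorted by (chrom, pos).
#' @param penalty breakpoint penalty (> 0); default `10 * sigma^2`.
#' @param min_probes minimum probes per segment (>= 2).
#' @return data.frame of segments: chrom, start, end (first/last probe
#'   positions, 1-based inclusive), n_probes, mean_lrr, state (NA; set by
#'   [call_states()]).  Empty track gives an empty frame.
#' @export
segment_lrr <- function(track, penalty = NULL, min_probes = 2L) {
  stopifnot(min_probes >= 2L)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      mean_lrr = numeric(0), state = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(track) || nrow(track) == 0L) return(empty)
  need <- c("chrom", "pos", "lrr")
  miss <- setdiff(need, names(track))
  if (length(miss))
    stop_invalid("track lacks columns: ", paste(miss, collapse = ", "))
  chroms <- unique(track$chrom)
  for (ch in chroms) {
    p <- track$pos[track$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop_invalid("track must be sorted by (chrom, pos) with strictly ",
                   "increasing positions; chromosome ", ch, " is not")
  }
  if (is.null(penalty)) {
    d <- unlist(lapply(chroms, function(ch) diff(track$lrr[track$chrom == ch])))
    sigma <- stats::median(abs(d)) / (0.6744898 * sqrt(2))
    penalty <- 10 * sigma^2
  }
  penalty <- max(penalty, 1e-9) # keep breakpoints strictly costly
  segs <- lapply(chroms, function(ch) {
    x <- track$lrr[track$chrom == ch]
    p <- track$pos[track$chrom == ch]
    bps <- opt_breakpoints(x, penalty, as.integer(min_probes))
    bounds <- c(0L, bps, length(x))
    do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(k) {
      i <- bounds[k] + 1L; j <- bounds[k + 1L]
      data.frame(chrom = ch, start = p[i], end = p[j],
                 n_probes = j - i + 1L, mean_lrr = mean(x[i:j]),
                 state = NA_character_, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# exact optimal partitioning: minimize RSS + penalty * (#breakpoints),
# segments >= min_probes probes; returns breakpoint indices (last probe of
# each non-final segment), possibly empty
opt_breakpoints <- function(x, penalty, min_probes) {
  n <- length(x)
  if (n < 2L * min_probes) return(integer(0))
  S1 <- cumsum(c(0, x)); S2 <- cumsum(c(0, x * x))
  # F[t+1] = best cost of x[1..t] counting penalty once per segment;
  # F[1] = -penalty makes the total RSS + penalty * (#segments - 1)
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  for (t in min_probes:n) {
    s <- 0:(t - min_probes)           # candidate previous ends; segment (s+1)..t
    ok <- is.finite(F[s + 1L])
    s <- s[ok]
    len <- t - s
    cost <- (S2[t + 1L] - S2[s + 1L]) - (S1[t + 1L] - S1[s + 1L])^2 / len
    tot <- F[s + 1L] + cost + penalty
    i <- which.min(tot)
    F[t + 1L] <- tot[i]
    prev[t + 1L] <- s[i]
  }
  bps <- integer(0); t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) bps <- c(s, bps)
    t <- s
  }
  bps
}

#' Call gain/loss/neutral states on LRR segments
#'
#' Strict thresholds: a segment is a gain iff `mean_lrr > gain_t`, a loss
#' iff `mean_lrr < loss_t`, otherwise neutral.  A segment sitting exactly
#' on a threshold is neutral.
#'
#' @param segments output of [segment_lrr()].
#' @param gain_t,loss_t LRR thresholds (defaults +0.10 / -0.15, permissive
#'   enough to catch mosaic events); `loss_t < 0 < gain_t` required.
#' @return the segments with `state` filled in; thresholds are recorded in
#'   the `thresholds` attribute.
#' @export
call_states <- function(segments, gain_t = 0.10, loss_t = -0.15) {
  if (!(loss_t < 0 && 0 < gain_t))
    stop_invalid("need loss_t < 0 < gain_t")
  st <- rep("neutral", nrow(segments))
  st[segments$mean_lrr > gain_t] <- "gain"
  st[segments$mean_lrr < loss_t] <- "loss"
  segments$state <- st
  attr(segments, "thresholds") <- c(gain_t = gain_t, loss_t = loss_t)
  segments
}

#' Detect copy-neutral LOH from BAF runs in neutral segments
#'
#' A CN-LOH call is a maximal run of at least `min_run` consecutive
#' informative probes (genotype called, i.e. not "NC") spanning at least
#' `min_span` bp in which no probe has BAF strictly inside the
#' heterozygous band `(lo, hi)`.  Runs are searched only inside
#' copy-neutral segments: the same BAF pattern inside a gain or loss
#' segment is never CN-LOH.  Adjacent neutral segments are merged into
#' maximal neutral extents before scanning, so a neutral-to-neutral
#' segmentation boundary cannot break a homozygous run.
#'
#' @param track per-sample probe table (probe_id, chrom, pos, lrr, baf,
#'   genotype), sorted by (chrom, pos).
#' @param segments state-called segments from [call_states()].
#' @param min_run minimum informative probes per run (default 50).
#' @param baf_het_band c(lo, hi) heterozygous BAF band
#'   (default c(0.15, 0.85)); `0 < lo < hi < 1`.
#' @param min_span minimum bp span (default 3e6).
#' @return data.frame of cnloh segments (chrom, start, end, n_probes,
#'   mean_lrr, state = "cnloh"); empty if none.
#' @export
detect_cnloh <- function(track, segments, min_run = 50L,
                         baf_het_band = c(0.15, 0.85), min_span = 3e6) {
  lo <- baf_het_band[1L]; hi <- baf_het_band[2L]
  if (!(0 < lo && lo < hi && hi < 1))
    stop_invalid("need 0 < lo < hi < 1 in baf_het_band")
  stopifnot(all(c("chrom", "pos", "baf", "genotype") %in% names(track)))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      mean_lrr = numeric(0), state = character(0),
                      stringsAsFactors = FALSE)
  neut <- segments[segments$state == "neutral", , drop = FALSE]
  if (nrow(neut) == 0L) return(empty)
  # merge adjacent neutral segments into maximal neutral extents
  neut <- neut[order(match(neut$chrom, unique(segments$chrom)),
                     neut$start), , drop = FALSE]
  merged <- neut[1L, , drop = FALSE]
  if (nrow(neut) > 1L) {
    for (k in 2L:nrow(neut)) {
      last <- nrow(merged)
      same <- neut$chrom[k] == merged$chrom[last]
      # contiguous iff no other segment sits between them
      between <- segments$chrom == neut$chrom[k] &
        segments$start > merged$end[last] & segments$end < neut$start[k] &
        segments$state != "neutral"
      if (same && !any(between)) {
        merged$end[last] <- neut$end[k]
        merged$n_probes[last] <- merged$n_probes[last] + neut$n_probes[k]
      } else {
        merged <- rbind(merged, neut[k, , drop = FALSE])
      }
    }
  }
  neut <- merged
  calls <- list()
  for (k in seq_len(nrow(neut))) {
    idx <- which(track$chrom == neut$chrom[k] &
                   track$pos >= neut$start[k] & track$pos <= neut$end[k] &
                   track$genotype != "NC")
    if (length(idx) < min_run) next
    outside <- !(track$baf[idx] > lo & track$baf[idx] < hi)
    r <- rle(outside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (m in which(r$values & r$lengths >= min_run)) {
      i <- idx[starts[m]]; j <- idx[ends[m]]
      span <- track$pos[j] - track$pos[i] + 1
      if (span < min_span) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = neut$chrom[k], start = track$pos[i], end = track$pos[j],
        n_probes = ends[m] - starts[m] + 1L,
        mean_lrr = mean(track$lrr[i:j]), state = "cnloh",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Per-sample chromosomal-abnormality burden ratio
#'
#' The burden is the fraction of the probed autosomal genome in an
#' aberrant state: `frac_gain_loss` is the bp in gain or loss segments
#' over the basis, `frac_cnloh` the bp in CN-LOH calls over the basis, and
#' `frac_total` their sum — the combined ratio of copy-number-altering and
#' copy-neutral changes.  Sex chromosomes are excluded; non-autosomal
#' segments and basis rows are dropped.
#'
#' @param segments state-called segments, including cnloh rows (e.g.
#'   `rbind(call_states(...), detect_cnloh(...))`).  Segment bp is
#'   `end - start + 1` (probe-delimited, 1-based inclusive).
#' @param basis per-chromosome probed extent: data.frame(chrom, start,
#'   end).  Usually [probed_extent()] of the track.
#' @param sample_id optional sample label.
#' @return one-row data.frame: sample_id, frac_gain_loss, frac_cnloh,
#'   frac_total, basis_bp.
#' @export
burden_ratio <- function(segments, basis, sample_id = NA_character_) {
  stopifnot(all(c("chrom", "start", "end") %in% names(basis)))
  basis <- basis[is_autosome(basis$chrom), , drop = FALSE]
  basis_bp <- sum(basis$end - basis$start + 1)
  if (!(basis_bp > 0)) stop_invalid("basis_bp must be > 0")
  seg <- segments[is_autosome(segments$chrom), , drop = FALSE]
  bp <- seg$end - seg$start + 1
  gl <- sum(bp[seg$state %in% c("gain", "loss")])
  cn <- sum(bp[seg$state == "cnloh"])
  data.frame(sample_id = sample_id,
             frac_gain_loss = gl / basis_bp,
             frac_cnloh = cn / basis_bp,
             frac_total = (gl + cn) / basis_bp,
             basis_bp = basis_bp,
             stringsAsFactors = FALSE)
}

#' Probed extent of a track (first to last probe per chromosome)
#' @param track probe table with chrom and pos.
#' @return data.frame(chrom, start, end).
#' @export
probed_extent <- function(track) {
  agg <- lapply(split(track$pos, track$chrom), range)
  data.frame(chrom = names(agg),
             start = vapply(agg, `[`, numeric(1), 1L),
             end = vapply(agg, `[`, numeric(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full CNV calling chain for one sample
#'
#' Convenience wrapper: segment LRR, call states, detect CN-LOH and
#' compute the burden ratio with the probed extent as basis.
#'
#' @param track per-sample probe table.
#' @param sample_id sample label for the report.
#' @param penalty,min_probes see [segment_lrr()].
#' @param gain_t,loss_t see [call_states()].
#' @param min_run,baf_het_band,min_span see [detect_cnloh()].
#' @return list(segments, cnloh, burden).
#' @export
call_cnv_sample <- function(track, sample_id = NA_character_,
                            penalty = NULL, min_probes = 2L,
                            gain_t = 0.10, loss_t = -0.15,
                            min_run = 50L, baf_het_band = c(0.15, 0.85),
                            min_span = 3e6) {
  segs <- call_states(segment_lrr(track, penalty, min_probes), gain_t, loss_t)
  cnloh <- detect_cnloh(track, segs, min_run, baf_het_band, min_span)
  burden <- burden_ratio(rbind(segs, cnloh), probed_extent(track), sample_id)
  list(segments = segs, cnloh = cnloh, burden = burden)
}
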