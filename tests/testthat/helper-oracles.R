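# Independent oracles and small fixture builders used across tests.

# Exhaustive penalized-least-squares segmentation: enumerate every
# breakpoint subset (bitmask over the n-1 cut points), respecting the
# minimum segment length, and return the optimal cost.  Only feasible for
# small n; this is the brute-force reference the fast implementation is
# checked against.
exhaustive_segment <- function(x, penalty, min_probes = 2L) {
  n <- length(x)
  S1 <- cumsum(c(0, x)); S2 <- cumsum(c(0, x * x))
  segrss <- function(i, j) S2[j + 1] - S2[i] - (S1[j + 1] - S1[i])^2 / (j - i + 1)
  best <- Inf; best_bps <- integer(0)
  pow <- 2^(0:(n - 2))
  for (mask in 0:(2^(n - 1) - 1)) {
    bps <- which(bitwAnd(mask, pow) != 0)
    bounds <- c(0L, bps, n)
    if (any(diff(bounds) < min_probes)) next
    rss <- 0
    for (k in seq_len(length(bounds) - 1L))
      rss <- rss + segrss(bounds[k] + 1L, bounds[k + 1L])
    cost <- rss + penalty * length(bps)
    if (cost < best - 1e-12) { best <- cost; best_bps <- bps }
  }
  list(cost = best, bps = best_bps)
}

# Penalized cost of a segmentation as returned by segment_lrr(), for one
# chromosome's track.
segmentation_cost <- function(x, pos, segs, penalty) {
  rss <- 0
  for (k in seq_len(nrow(segs))) {
    xi <- x[pos >= segs$start[k] & pos <= segs$end[k]]
    rss <- rss + sum((xi - mean(xi))^2)
  }
  rss + penalty * (nrow(segs) - 1L)
}

# Row-wise one-way ANOVA via stats::oneway.test (the textbook
# between/within mean-square ratio), as the independent reference for the
# vectorised implementation.
oneway_oracle <- function(mat, groups) {
  g <- factor(groups)
  res <- t(apply(mat, 1L, function(x) {
    ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
    c(f = unname(ft$statistic), p = unname(ft$p.value))
  }))
  data.frame(f = res[, "f"], p = res[, "p"])
}

# Minimal track builder: one chromosome, evenly spaced probes.
make_track <- function(lrr, baf = rep(0.5, length(lrr)),
                       genotype = rep("AB", length(lrr)),
                       chrom = "1", spacing = 10000) {
  n <- length(lrr)
  data.frame(probe_id = sprintf("p%05d", seq_len(n)), chrom = chrom,
             pos = (seq_len(n) - 1) * spacing + 1, lrr = lrr, baf = baf,
             genotype = genotype, stringsAsFactors = FALSE)
}

# Tiny 3x3(+groups) matrix builder with named samples matching a design.
tissue_design <- function(n = 3L) default_design(n, 0L)
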