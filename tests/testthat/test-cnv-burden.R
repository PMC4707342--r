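test_that("constant LRR yields one segment per chromosome", {
  tr <- rbind(make_track(rep(0.1, 40), chrom = "1"),
              make_track(rep(-0.2, 30), chrom = "2"))
  segs <- segment_lrr(tr)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_probes, c(40L, 30L))
  expect_equal(segs$mean_lrr, c(0.1, -0.2))
})

test_that("segmentation equals the exhaustive optimum on small tracks", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    x <- rnorm(n, 0, 0.2)
    if (i %% 2 == 0) { # half the instances carry a real step
      cp <- sample(2:(n - 2), 1)
      x[(cp + 1):n] <- x[(cp + 1):n] + runif(1, 0.3, 1)
    }
    pen <- runif(1, 0.05, 0.5)
    tr <- make_track(x)
    segs <- segment_lrr(tr, penalty = pen, min_probes = 2)
    impl <- segmentation_cost(x, tr$pos, segs, pen)
    oracle <- exhaustive_segment(x, pen, 2L)$cost
    expect_equal(impl, oracle, tolerance = 1e-9)
  }
})

test_that("a planted step is located within a few probes under noise", {
  hits <- 0L
  n <- 1000L
  for (s in 1:100) {
    set.seed(1000 + s)
    x <- rnorm(n, 0, 0.1)
    x[501:n] <- x[501:n] + 0.5
    segs <- segment_lrr(make_track(x))
    # breakpoints in probe-index units; nearest one to the planted step
    bps <- (segs$end[-nrow(segs)] - 1) / 10000 + 1
    if (length(bps) && min(abs(bps - 500)) <= 3) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("unsorted or malformed tracks are rejected", {
  tr <- make_track(rnorm(10))
  tr2 <- tr[c(2, 1, 3:10), ]
  expect_error(segment_lrr(tr2), "sorted")
  expect_equal(nrow(segment_lrr(tr[0, ])), 0L)
  expect_error(segment_lrr(tr, min_probes = 1L))
})

test_that("state calling uses strict thresholds", {
  segs <- data.frame(chrom = "1", start = 1, end = 100, n_probes = 10,
                     mean_lrr = c(0, 0.40, 0.10, -0.15, -0.30),
                     state = NA_character_)
  segs$start <- c(1, 101, 201, 301, 401) # keep rows distinct
  out <- call_states(segs, gain_t = 0.10, loss_t = -0.15)
  expect_equal(out$state, c("neutral", "gain", "neutral", "neutral", "loss"))
  expect_error(call_states(segs, gain_t = -0.1, loss_t = -0.2))
})

test_that("CN-LOH calls require homozygous runs in neutral segments", {
  # all heterozygous: no calls
  tr <- make_track(rep(0, 300), baf = rep(0.5, 300), spacing = 20000)
  segs <- call_states(segment_lrr(tr))
  expect_equal(nrow(detect_cnloh(tr, segs)), 0L)

  # 200-probe homozygous run at neutral LRR: one covering call
  baf <- rep(0.5, 300)
  baf[51:250] <- rep(c(0.02, 0.98), 100)
  tr <- make_track(rep(0, 300), baf = baf, spacing = 20000)
  segs <- call_states(segment_lrr(tr))
  calls <- detect_cnloh(tr, segs, min_run = 50, min_span = 3e6)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_probes, 200L)
  expect_equal(calls$start, tr$pos[51])
  expect_equal(calls$end, tr$pos[250])

  # the same BAF pattern inside a loss segment is never CN-LOH
  lrr <- rep(0, 300); lrr[51:250] <- -0.6
  tr <- make_track(lrr, baf = baf, spacing = 20000)
  segs <- call_states(segment_lrr(tr, penalty = 0.5))
  expect_true("loss" %in% segs$state)
  expect_equal(nrow(detect_cnloh(tr, segs, min_run = 50, min_span = 3e6)), 0L)
})

test_that("burden ratio arithmetic matches the sum definition", {
  basis <- data.frame(chrom = "1", start = 1, end = 1e8)
  none <- data.frame(chrom = "1", start = 1, end = 1e8, n_probes = 10,
                     mean_lrr = 0, state = "neutral")
  expect_equal(burden_ratio(none, basis)$frac_total, 0)

  segs <- data.frame(chrom = "1", start = c(1, 2e7), end = c(1e7, 2.5e7 - 1),
                     n_probes = 10, mean_lrr = c(0.4, 0),
                     state = c("gain", "cnloh"))
  rep_ <- burden_ratio(segs, basis)
  expect_equal(rep_$frac_gain_loss, 0.1)
  expect_equal(rep_$frac_cnloh, 0.05)
  expect_equal(rep_$frac_total, 0.15)
  expect_equal(rep_$frac_total, rep_$frac_gain_loss + rep_$frac_cnloh)

  whole <- data.frame(chrom = "1", start = 1, end = 1e8, n_probes = 10,
                      mean_lrr = -0.6, state = "loss")
  expect_equal(burden_ratio(whole, basis)$frac_total, 1.0)
})

test_that("burden ratio ignores sex chromosomes and segment subdivision", {
  basis <- data.frame(chrom = c("1", "X"), start = 1, end = 1e8)
  seg_x <- data.frame(chrom = "X", start = 1, end = 1e8, n_probes = 10,
                      mean_lrr = 0.4, state = "gain")
  expect_equal(burden_ratio(seg_x, basis)$frac_total, 0)
  expect_equal(burden_ratio(seg_x, basis)$basis_bp, 1e8)

  one <- data.frame(chrom = "1", start = 1, end = 4e7, n_probes = 10,
                    mean_lrr = 0.4, state = "gain")
  two <- data.frame(chrom = "1", start = c(1, 2e7 + 1), end = c(2e7, 4e7),
                    n_probes = 5, mean_lrr = 0.4, state = "gain")
  expect_equal(burden_ratio(one, basis)$frac_total,
               burden_ratio(two, basis)$frac_total)
})

test_that("planted three-state profiles are recovered end to end", {
  d <- tissue_design()
  ab <- list(LMS1 = plant_burden_profile(0.5))
  snp <- generate_snp_array(d, ab, noise_sd = 0.15, seed = 77)
  res <- call_cnv_sample(snp$tracks$LMS1, "LMS1")
  planted <- snp$truth$burden[snp$truth$burden$sample_id == "LMS1", ]
  expect_lt(abs(res$burden$frac_total - planted$frac_total), 0.03)
  expect_gt(res$burden$frac_cnloh, 0)
})
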