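test_that("beta formula matches the array definition", {
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 0), 0.9)
  expect_equal(compute_beta(300, 300), 300 / 700)
  expect_true(all(compute_beta(c(0, 1e6), c(1e6, 0)) < 1))
  expect_error(compute_beta(-1, 5), "non-negative")
})

test_that("QC drops a probe failing in any sample", {
  b <- matrix(0.5, 3, 3, dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  p <- matrix(0.01, 3, 3, dimnames = dimnames(b))
  qc <- qc_filter(b, p)
  expect_equal(qc$n_kept, 3L)
  expect_identical(qc$beta, b)

  p2 <- p; p2[2, 3] <- 0.06
  qc2 <- qc_filter(b, p2)
  expect_equal(qc2$removed, "p2")

  b3 <- b; b3[1, 1] <- NA
  qc3 <- qc_filter(b3, p)
  expect_equal(qc3$removed, "p1")
})

test_that("delta-beta classification is strict at +/-0.2", {
  d <- tissue_design()
  b <- matrix(0.5, 4, 9, dimnames = list(paste0("p", 1:4), d$sample_id))
  b[2, d$group == "LMS"] <- 0.8                  # delta 0.3 -> hyper
  b[3, d$group == "LMS"] <- 0.7                  # delta exactly 0.2
  b[4, d$group == "LMS"] <- 0.1                  # delta -0.4 -> hypo
  calls <- group_delta_beta(b, d, "LMS", "NM")
  expect_equal(calls$status, c("none", "hyper", "none", "hypo"))
  expect_equal(calls$delta_beta, c(0, 0.3, 0.2, -0.4), tolerance = 1e-12)
})

test_that("feature/CGI tabulation partitions the probe universe", {
  man <- make_manifest(15, seed = 3)
  probes <- man$probe_id
  status <- rep("none", length(probes))
  tss200 <- which(man$feature_group == "TSS200")[1:10]
  status[tss200] <- "hyper"
  calls <- data.frame(probe_id = probes, delta_beta = 0, status = status)
  tab <- tabulate_by_feature(calls, man)
  f <- tab$feature
  expect_equal(f$n_hyper[f$category == "TSS200"], 10L)
  expect_equal(sum(f$n_hyper[f$category != "Total"]), 10L)
  # partition: category counts sum to the grand total in both tables
  expect_equal(sum(f$n_probes[f$category != "Total"]),
               f$n_probes[f$category == "Total"])
  g <- tab$cgi
  expect_equal(sum(g$n_probes[g$category != "Total"]),
               g$n_probes[g$category == "Total"])
  expect_equal(f$n_probes[f$category == "Total"],
               g$n_probes[g$category == "Total"])
  expect_error(tabulate_by_feature(
    data.frame(probe_id = "missing", delta_beta = 0, status = "none"), man),
    "missing")
})

test_that("region binning needs >= 2 same-feature probes of one gene", {
  man <- data.frame(
    probe_id = paste0("p", 1:5),
    chrom = "1", pos = c(100, 180, 300, 5000, 9000),
    gene = c("X", "X", "X", "X", "Y"),
    feature_group = c("TSS200", "TSS200", "TSS1500", "Body", "Body"),
    cgi_relation = "island", stringsAsFactors = FALSE)
  calls <- data.frame(probe_id = paste0("p", 1:5), delta_beta = 0.4,
                      status = c("hyper", "hyper", "hyper", "hyper", "hyper"))
  reg <- bin_regions(calls, man, "hyper")
  # X/TSS200 has two probes -> one region; TSS1500 and Body singletons drop
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$gene, "X")
  expect_equal(reg$feature_group, "TSS200")
  expect_equal(reg$n_probes, 2L)
  expect_equal(c(reg$start, reg$end), c(100, 180))

  calls2 <- calls; calls2$status[2] <- "none"
  expect_equal(nrow(bin_regions(calls2, man, "hyper")), 0L)
})

test_that("two-sided beta marker filter is strict and refines to promoters", {
  d <- tissue_design()
  b <- matrix(0.5, 3, 9, dimnames = list(paste0("p", 1:3), d$sample_id))
  b[1, ] <- c(rep(0.3, 3), c(0.05, 0.02, 0.09), c(0.7, 0.8, 0.9))
  b[2, ] <- c(rep(0.3, 3), c(0.05, 0.02, 0.09), c(0.7, 0.8, 0.55))
  b[3, ] <- c(rep(0.3, 3), c(0.7, 0.9, 0.8), c(0.05, 0.01, 0.02))
  mk <- select_methylation_markers(b, d, "LMS", "LM")
  expect_equal(mk$direction[mk$probe_id == "p1"], "hyper_in_LMS")
  expect_false("p2" %in% mk$probe_id) # 0.55 <= 0.6 fails the strict filter
  expect_equal(mk$direction[mk$probe_id == "p3"], "hyper_in_LM")

  man <- data.frame(probe_id = paste0("p", 1:3), chrom = "1",
                    pos = c(100, 150, 300), gene = "NPAS4like",
                    feature_group = c("TSS200", "TSS200", "TSS1500"),
                    cgi_relation = "island", stringsAsFactors = FALSE)
  # two passing promoter probes of one gene in the same direction
  mk2 <- data.frame(probe_id = c("p1", "p2"),
                    direction = "hyper_in_LMS", stringsAsFactors = FALSE)
  ref <- promoter_refine(mk2, man)
  expect_equal(ref$gene, "NPAS4like")
  expect_equal(ref$n_probes, 2L)
  # a single promoter probe is not enough
  expect_equal(nrow(promoter_refine(mk2[1, ], man)), 0L)
})

test_that("gene-set overlap counts and fractions", {
  expect_equal(geneset_overlap(c("a", "b"), c("c", "d")),
               list(count = 0L, fraction = 0))
  expect_equal(geneset_overlap(c("a", "b", "c"), c("a", "b"))$fraction, 1.0)
  ref <- sprintf("r%04d", 1:1893)
  dm <- c(ref[1:197], sprintf("x%04d", 1:500))
  ov <- geneset_overlap(dm, ref)
  expect_equal(ov$count, 197L)
  expect_equal(round(ov$fraction, 3), 0.104)
  expect_error(geneset_overlap("a", character(0)), "empty")
})

test_that("global beta stats summarise samples and groups", {
  d <- tissue_design()
  b <- matrix(0.5, 10, 9, dimnames = list(paste0("p", 1:10), d$sample_id))
  gs <- global_stats(b, d)
  expect_true(all(gs$samples$median == 0.5))
  expect_equal(unname(gs$group_medians["LMS"]), 0.5)
  expect_error(global_stats(b[0, ], d), "empty")
})

test_that("DM calls are invariant to probe and sample ordering", {
  d <- tissue_design()
  man <- make_manifest(10, seed = 4)
  meth <- generate_methylation(
    d, man, dm_spec = dm_spec_sample(man, "LMS", 0.4, 20, seed = 4),
    noise_sd = 0.2, fail_rate = 0, seed = 9)
  calls <- group_delta_beta(meth$beta, d, "LMS", "NM")
  perm <- sample(nrow(meth$beta))
  permc <- sample(ncol(meth$beta))
  calls2 <- group_delta_beta(meth$beta[perm, permc], d, "LMS", "NM")
  m1 <- calls[order(calls$probe_id), ]
  m2 <- calls2[order(calls2$probe_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})
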