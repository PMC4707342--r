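test_that("quantile normalization maps columns to per-rank means", {
  m <- cbind(a = c(1, 3), b = c(3, 5))
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(2, 4), c(2, 4)))

  # identical columns are unchanged
  m2 <- cbind(a = c(2, 7, 4), b = c(2, 7, 4))
  expect_equal(quantile_normalize(m2), m2)

  # columns that permute one multiset end up identical up to ordering
  set.seed(1)
  v <- rnorm(50)
  m3 <- cbind(a = v, b = sample(v), c = sample(v))
  out3 <- quantile_normalize(m3)
  for (j in 1:3) expect_equal(sort(out3[, j]), sort(v))
  expect_equal(order(out3[, 2]), order(m3[, 2]))
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "2 samples")
})

test_that("row-wise ANOVA matches the direct F formula", {
  d <- default_design(3, 3)
  set.seed(7)
  mat <- matrix(rnorm(30 * 12, 8), 30, 12,
                dimnames = list(sprintf("p%02d", 1:30), d$sample_id))
  mat[1:5, d$group == "LMS"] <- mat[1:5, d$group == "LMS"] + 3
  res <- anova_bh(mat, d)
  oracle <- oneway_oracle(mat, d$group)
  expect_equal(res$f_stat, oracle$f, tolerance = 1e-9)
  expect_equal(res$p, oracle$p, tolerance = 1e-9)
  expect_equal(res$q, p.adjust(oracle$p, "BH"), tolerance = 1e-9)
  expect_true(all(res$q >= res$p))
})

test_that("degenerate ANOVA rows follow the stated conventions", {
  d <- tissue_design()
  mat <- matrix(5, 4, 9, dimnames = list(paste0("p", 1:4), d$sample_id))
  res <- anova_bh(mat, d)
  expect_true(all(res$f_stat == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$selected))
  d5 <- group_design(c("NM1", "NM2", "LM1", "LM2", "LMS1"),
                     c("NM", "NM", "LM", "LM", "LMS"))
  m5 <- matrix(rnorm(10), 2, 5, dimnames = list(c("a", "b"), d5$sample_id))
  expect_error(anova_bh(m5, d5), "2 samples")
})

test_that("fold-change filter is strict at the threshold", {
  means <- rbind(p1 = c(NM = 10, LM = 10, LMS = 25),   # FC 2.5 vs NM
                 p2 = c(NM = 10, LM = 20, LMS = 20),   # FC exactly 2
                 p3 = c(NM = 10, LM = 4, LMS = 10))    # FC 0.4 (LM/NM)
  sel <- data.frame(probe_id = c("p1", "p2", "p3"))
  out <- fold_change_filter(sel, means, fc = 2)
  expect_setequal(out$probe_id, c("p1", "p3"))
  expect_error(fold_change_filter(sel, means - 20), "> 0")
})

test_that("symbol dedup keeps the strongest probe and drops unannotated", {
  sel <- data.frame(probe_id = c("a", "b", "c", "d"),
                    fc_LMS_vs_NM = c(4, 8, 2, 0.2),
                    stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = c("a", "b", "c", "d"),
                    symbol = c("G1", "G1", NA, "G2"),
                    stringsAsFactors = FALSE)
  out <- dedup_by_symbol(sel, ann)
  expect_setequal(out$symbol, c("G1", "G2"))
  expect_equal(out$probe_id[out$symbol == "G1"], "b") # |log2 8| > |log2 4|
  # tie in |log2 FC| resolved by lexicographic probe_id
  sel2 <- data.frame(probe_id = c("z9", "a1"), fc_LMS_vs_NM = c(4, 0.25),
                     stringsAsFactors = FALSE)
  ann2 <- data.frame(probe_id = c("z9", "a1"), symbol = c("G", "G"),
                     stringsAsFactors = FALSE)
  expect_equal(dedup_by_symbol(sel2, ann2)$probe_id, "a1")
})

test_that("specific markers demand on-in-class and off-outside", {
  d <- tissue_design()
  mat <- rbind(m1 = c(rep(4, 6), rep(9, 3)),   # LMS-specific
               m2 = c(rep(9, 6), rep(4, 3)),   # NM/LM-specific
               m3 = rep(9, 9),                 # on everywhere: no class
               m4 = c(rep(4, 3), rep(9, 6)))   # LM/LMS-specific
  colnames(mat) <- d$sample_id
  flags <- ifelse(mat > 6, "present", "absent")
  out <- select_specific_markers(mat, flags, d)
  expect_equal(out$class[out$probe_id == "m1"], "LMS")
  expect_equal(out$class[out$probe_id == "m2"], "NM/LM")
  expect_equal(out$class[out$probe_id == "m4"], "LM/LMS")
  expect_false("m3" %in% out$probe_id)
})

test_that("planted class-specific markers are recovered exactly at zero noise", {
  d <- default_design(3, 3)
  spec <- data.frame(class = c("LMS", "NM/LM"), n = c(12, 5))
  expr <- generate_expression(d, n_probes = 500, marker_spec = spec,
                              sample_sd = 0, seed = 31)
  log2m <- log2(quantile_normalize(expr$intensity))
  out <- select_specific_markers(log2m, expr$flags, d)
  truth <- expr$truth$markers
  # each planted class is recovered exactly: no planted probe missed, no
  # null probe assigned to a planted class
  for (cl in unique(truth$class)) {
    expect_setequal(out$probe_id[out$class == cl],
                    truth$probe_id[truth$class == cl])
  }
})

test_that("DE counts versus the reference mean and common fractions", {
  d <- tissue_design()
  mat <- matrix(10, 20, 9, dimnames = list(sprintf("g%02d", 1:20),
                                           d$sample_id))
  # all LMS samples share the same 5 upregulated probes
  mat[1:5, d$group == "LMS"] <- 30
  # each LM sample has its own single downregulated probe
  lm_cols <- which(d$group == "LM")
  for (k in seq_along(lm_cols)) mat[5 + k, lm_cols[k]] <- 2
  res <- count_de_vs_reference(mat, d)
  counts <- res$counts
  expect_true(all(counts$n_up[counts$group == "LMS"] == 5))
  expect_true(all(counts$n_down[counts$group == "LM"] == 1))
  common <- res$common
  expect_equal(common$common_up[common$group == "LMS"], 1.0)
  expect_equal(common$common_down[common$group == "LM"], 0)
  # a sample identical to the reference mean has no DE probes
  expect_true(all(counts$n_up[counts$group == "LM"] == 0))
  expect_error(count_de_vs_reference(mat, d, reference_group = "CELL"),
               "empty")
})
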