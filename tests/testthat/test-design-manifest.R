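test_that("group design enforces unique samples and core groups", {
  d <- group_design(c("NM1", "LM1", "LMS1"), c("NM", "LM", "LMS"))
  expect_s3_class(d, "group_design")
  expect_error(group_design(c("a", "a", "b"), c("NM", "LM", "LMS")),
               "duplicated")
  expect_error(group_design(c("a", "b"), c("NM", "XX")), "unknown group")
  expect_error(group_design(c("a", "b"), c("NM", "LM")), "LMS")
  expect_equal(design_samples(default_design(3, 2), "CELL"),
               c("CELL1", "CELL2"))
})

test_that("manifest feature categories partition the probe set", {
  ppf <- c(TSS200 = 2L, TSS1500 = 2L, UTR5_1stExon = 2L, Body = 4L,
           UTR3 = 1L, Intergenic = 3L)
  man <- make_manifest(20, probes_per_feature = ppf, cgi_fraction = 0.3,
                       seed = 5)
  expect_equal(nrow(man), 20 * sum(ppf))
  # exactly one feature group and one CGI relation per probe, counts sum
  expect_equal(sum(table(man$feature_group)), nrow(man))
  expect_equal(as.integer(table(man$feature_group)[FEATURE_LEVELS]),
               as.integer(20 * ppf[FEATURE_LEVELS]))
  expect_equal(sum(table(man$cgi_relation)), nrow(man))
  expect_false(anyDuplicated(man$probe_id) > 0)
  # intergenic probes carry no gene
  expect_true(all(is.na(man$gene[man$feature_group == "Intergenic"])))
  expect_true(all(!is.na(man$gene[man$feature_group != "Intergenic"])))
})

test_that("manifest coordinates are consistent with the TSS layout", {
  man <- make_manifest(10, seed = 2)
  for (g in unique(na.omit(man$gene))) {
    m <- man[!is.na(man$gene) & man$gene == g, ]
    t1500 <- m$pos[m$feature_group == "TSS1500"]
    t200 <- m$pos[m$feature_group == "TSS200"]
    down <- m$pos[m$feature_group %in% c("UTR5_1stExon", "Body", "UTR3")]
    # upstream windows are disjoint and ordered: TSS1500 < TSS200 < gene
    expect_true(max(t1500) < min(t200))
    expect_true(max(t200) < min(down))
    # TSS200 probes sit within 200 bp, TSS1500 within 200-1500 bp upstream
    expect_lte(diff(range(t200)), 200)
    expect_lte(diff(range(t1500)), 1300)
  }
})

test_that("zero CGI fraction gives an all-open-sea manifest", {
  man <- make_manifest(5, cgi_fraction = 0, seed = 1)
  expect_true(all(man$cgi_relation == "open_sea"))
})

test_that("manifest generation is deterministic and validates inputs", {
  expect_identical(make_manifest(8, seed = 9), make_manifest(8, seed = 9))
  expect_error(make_manifest(0), "n_genes")
  bad <- c(TSS200 = 0L, TSS1500 = 2L, UTR5_1stExon = 2L, Body = 4L,
           UTR3 = 1L, Intergenic = 3L)
  expect_error(make_manifest(5, probes_per_feature = bad), "positive")
})
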