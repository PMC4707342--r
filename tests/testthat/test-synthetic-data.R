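test_that("noiseless SNP tracks are exact: LRR 0, BAF in {0, 1/2, 1}", {
  d <- tissue_design()
  snp <- generate_snp_array(d, probes_per_chrom = 50, n_chrom = 2,
                            noise_sd = 0, seed = 3)
  for (tr in snp$tracks) {
    expect_true(all(tr$lrr == 0))
    expect_true(all(tr$baf %in% c(0, 0.5, 1)))
  }
})

test_that("a full-clonality gain shifts LRR by exactly the gain constant", {
  d <- tissue_design()
  ab <- list(LMS1 = aberration_spec("1", 1, 200001, "gain", 1))
  snp <- generate_snp_array(d, ab, probes_per_chrom = 100, n_chrom = 1,
                            probe_spacing = 10000, noise_sd = 0, seed = 3)
  tr <- snp$tracks$LMS1
  inside <- tr$pos <= 200001
  expect_true(all(tr$lrr[inside] == 0.40))
  expect_true(all(tr$lrr[!inside] == 0))
  # heterozygous BAF splits to 0.5 +/- f/(4-2f), i.e. +/- 0.5 at f = 1
  het_in <- inside & tr$genotype == "AB"
  expect_true(all(tr$baf[het_in] %in% c(0, 1)))
  # at half clonality the split is f/(4-2f) = 1/6
  ab2 <- list(LMS1 = aberration_spec("1", 1, 200001, "gain", 0.5))
  tr2 <- generate_snp_array(d, ab2, probes_per_chrom = 100, n_chrom = 1,
                            probe_spacing = 10000, noise_sd = 0,
                            seed = 3)$tracks$LMS1
  het2 <- tr2$pos <= 200001 & tr2$genotype == "AB"
  expect_true(all(abs(abs(tr2$baf[het2] - 0.5) - 1 / 6) < 1e-12))
})

test_that("overlapping aberrations are rejected", {
  ab <- rbind(aberration_spec("1", 1, 1000, "gain", 1),
              aberration_spec("1", 500, 2000, "loss", 1))
  expect_error(validate_aberrations(ab), "overlap")
  expect_error(aberration_spec("1", 10, 5, "gain", 1), "start > end")
  expect_error(aberration_spec("1", 1, 10, "gain", 0), "mosaic")
})

test_that("generators are deterministic under a fixed seed", {
  d <- tissue_design()
  s1 <- generate_snp_array(d, probes_per_chrom = 30, n_chrom = 2, seed = 11)
  s2 <- generate_snp_array(d, probes_per_chrom = 30, n_chrom = 2, seed = 11)
  expect_identical(s1$tracks, s2$tracks)
  e1 <- generate_expression(d, n_probes = 200, seed = 11)
  e2 <- generate_expression(d, n_probes = 200, seed = 11)
  expect_identical(e1$intensity, e2$intensity)
  man <- make_manifest(5, seed = 1)
  m1 <- generate_methylation(d, man, seed = 11)
  m2 <- generate_methylation(d, man, seed = 11)
  expect_identical(m1$beta, m2$beta)
  c1 <- generate_cobra(c(A = 0.4), band_noise = 2, seed = 11)
  c2 <- generate_cobra(c(A = 0.4), band_noise = 2, seed = 11)
  expect_identical(c1$bands, c2$bands)
})

test_that("expression flags co-occur with near-background intensity", {
  d <- tissue_design()
  expr <- generate_expression(d, n_probes = 300,
                              marker_spec = data.frame(class = "LMS", n = 20),
                              seed = 4)
  absent <- expr$flags == "absent"
  expect_true(all(log2(expr$intensity[absent]) <= 6))
  expect_true(all(log2(expr$intensity[!absent]) > 6))
  expect_error(generate_expression(d, 100,
                                   de_spec = data.frame(group = "CELL", n = 5,
                                                        fc = 2)),
               "unknown group")
  expect_error(generate_expression(d, 100,
                                   de_spec = data.frame(group = "LMS", n = 5,
                                                        fc = -1)),
               "> 0")
})

test_that("methylation generator: betas in range and consistent with M/U", {
  d <- tissue_design()
  man <- make_manifest(20, seed = 2)
  meth <- generate_methylation(d, man, noise_sd = 0.3, seed = 5)
  expect_true(all(meth$beta >= 0 & meth$beta < 1))
  expect_equal(meth$beta, compute_beta(meth$M, meth$U), tolerance = 1e-12)
  expect_error(
    generate_methylation(d, man,
                         dm_spec = data.frame(probe_id = "nope",
                                              group = "LMS",
                                              delta_beta = 0.3)),
    "absent from manifest")
})

test_that("zero planted delta-beta at zero noise yields no DM calls", {
  d <- tissue_design()
  man <- make_manifest(10, seed = 2)
  meth <- generate_methylation(d, man, noise_sd = 0, fail_rate = 0, seed = 5)
  calls <- group_delta_beta(meth$beta, d, "LMS", "NM")
  expect_true(all(calls$status == "none"))
  expect_true(all(calls$delta_beta == 0))
})

test_that("blank beta cells are dropped by QC", {
  d <- tissue_design()
  man <- make_manifest(10, seed = 2)
  meth <- generate_methylation(d, man, blank_rate = 0.02, fail_rate = 0,
                               seed = 6)
  qc <- qc_filter(meth$beta, meth$detection_p)
  blanked <- rownames(meth$beta)[rowSums(is.na(meth$beta)) > 0]
  expect_true(all(blanked %in% qc$removed))
  expect_equal(qc$n_kept, nrow(meth$beta) - length(blanked))
})

test_that("COBRA generator honours the distortion curve", {
  z <- generate_cobra(c(A = 0), band_noise = 0)
  expect_equal(z$bands$cut_intensity, 0)
  h <- generate_cobra(c(A = 0.5), band_noise = 0)
  expect_equal(methylation_index(h$bands$cut_intensity,
                                 h$bands$uncut_intensity), 50)
  expect_error(generate_cobra(c(A = 0.5),
                              distortion = c(slope = -1, intercept = 0)),
               "slope")
})
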