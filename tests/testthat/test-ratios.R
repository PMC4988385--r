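test_that("raw ratios divide peak heights and invalidate non-positive peaks", {
  expect_equal(raw_ratio(1000, 1000), 1.0)
  expect_equal(raw_ratio(1200, 1000), 1.2)
  expect_true(is.na(raw_ratio(500, 0)))
  expect_true(is.na(raw_ratio(0, 500)))
  expect_equal(raw_ratio(c(1200, 900), c(1000, 1000)), c(1.2, 0.9))
})

test_that("plate correction factor is the mean gDNA ratio; empty plate errors", {
  expect_equal(plate_correction_factor(c(1, 1, 1))$correction_factor, 1)
  expect_equal(plate_correction_factor(c(0.8, 1.2))$correction_factor, 1)
  pc <- plate_correction_factor(c(0.9, 0.95, 1.0, 1.05), "P1", "rs3740387")
  expect_equal(pc$correction_factor, 0.975)
  expect_equal(pc$n_gdna, 4L)
  # NA (invalid) replicates are dropped before averaging
  expect_equal(plate_correction_factor(c(0.8, NA, 1.2))$n_gdna, 2L)
  expect_error(plate_correction_factor(c(NA_real_, NA_real_)), "unanalyzable")
})

test_that("corrected ratios divide by the plate factor", {
  expect_equal(corrected_ratio(1.17, 0.9), 1.3)
  expect_equal(corrected_ratio(0.9, 0.9), 1.0)
  expect_equal(corrected_ratio(1.23, 1.0), 1.23)
  pc <- plate_correction_factor(c(0.8, 1.2), "P1", "a")
  expect_equal(corrected_ratio(2, pc), 2)
})

test_that("replicate summaries use the n-1 SD and gate cDNA on CV 0.25", {
  s <- summarize_replicates(c(1.1, 1.1, 1.1, 1.1), "cDNA")
  expect_equal(s$mean_ratio, 1.1)
  expect_equal(s$cv, 0)
  expect_true(s$qc_pass)

  # hand evaluation of the sample-SD formula:
  # sd([1.0,1.5,0.5,1.0]) = sqrt((0 + .25 + .25 + 0)/3) = 0.40825
  s <- summarize_replicates(c(1.0, 1.5, 0.5, 1.0), "cDNA")
  expect_equal(s$mean_ratio, 1.0)
  expect_equal(s$sd_ratio, sqrt(0.5 / 3), tolerance = 1e-12)
  expect_equal(s$cv, sqrt(0.5 / 3), tolerance = 1e-12)
  expect_false(s$qc_pass)

  # the reproducibility filter applies to cDNA only
  expect_true(summarize_replicates(c(1.0, 1.5, 0.5, 1.0), "gDNA")$qc_pass)

  # fewer than two valid replicates -> unusable
  s <- summarize_replicates(c(1.2, NA, NA, NA), "cDNA")
  expect_false(s$usable)
  expect_true(is.na(s$mean_ratio))
})

test_that("percent effect converts mean ratios to signed percentages", {
  expect_equal(percent_effect(0.85), -15)  # a 15% reduction
  expect_equal(percent_effect(1.0), 0)
  expect_equal(percent_effect(0.88), -12)
  expect_equal(percent_effect(1.4), 40)
})

test_that("corrected gDNA ratios average exactly 1 on each plate by construction", {
  cohort <- simulate_cohort(sim_config(n_per_tissue = c(DLPFC = 30),
                                       assay_bias = 1.7, seed = 5))
  rs <- compute_ratio_summaries(cohort$peaks, cohort$samples)
  pk <- cohort$peaks
  pk$raw <- raw_ratio(pk$peak_a1, pk$peak_a2)
  for (i in seq_len(nrow(rs$corrections))) {
    co <- rs$corrections[i, ]
    sel <- pk$plate_id == co$plate_id & pk$assay_id == co$assay_id &
      pk$template == "gDNA"
    expect_equal(mean(pk$raw[sel] / co$correction_factor), 1, tolerance = 1e-12)
  }
})

test_that("plate correction removes any common allele-1 bias (scale invariance)", {
  base <- simulate_cohort(sim_config(n_per_tissue = c(DLPFC = 25),
                                     assay_bias = 1, seed = 8))
  biased <- base
  biased$peaks$peak_a1 <- biased$peaks$peak_a1 * 2.5
  s0 <- compute_ratio_summaries(base$peaks, base$samples)$summaries
  s1 <- compute_ratio_summaries(biased$peaks, biased$samples)$summaries
  expect_equal(s1$mean_ratio, s0$mean_ratio, tolerance = 1e-12)
  expect_equal(s1$cv, s0$cv, tolerance = 1e-10)
  expect_identical(s1$qc_pass, s0$qc_pass)
})

test_that("the QC decision is identical on raw and corrected ratios", {
  # cv = sd/mean is invariant under division by a positive scalar
  r <- c(1.05, 0.93, 1.4, 0.8)
  for (k in c(0.5, 1, 1.9)) {
    a <- summarize_replicates(r, "cDNA")
    b <- summarize_replicates(r / k, "cDNA")
    expect_equal(a$cv, b$cv, tolerance = 1e-12)
    expect_identical(a$qc_pass, b$qc_pass)
  }
})

test_that("ratio stage drops uninformative samples and logs exclusions", {
  samples <- tiny_samples()
  peaks <- tiny_peaks()
  # S3 is homozygous at the risk locus but heterozygous at the expressed
  # SNP: it must still be measured (informativeness is about the assay SNP)
  rs <- compute_ratio_summaries(peaks, samples)
  expect_setequal(unique(rs$summaries$sample_id), c("S1", "S2", "S3"))
  # make S3 homozygous at the expressed SNP: its peaks are dropped
  samples$rs3740387[3] <- "C/C"
  rs2 <- compute_ratio_summaries(peaks, samples)
  expect_setequal(unique(rs2$summaries$sample_id), c("S1", "S2"))
  expect_match(paste(rs2$log, collapse = " "), "not heterozygous")
})
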