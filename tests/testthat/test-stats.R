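test_that("Levene's test detects variance differences and matches the hand formula", {
  # identical absolute deviations -> W = 0, p = 1
  lv <- levene_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(lv["W"]), 0, tolerance = 1e-12)
  expect_equal(unname(lv["p"]), 1, tolerance = 1e-12)

  # strongly unequal spreads
  lv <- levene_test(c(0, 0, 0, 0), c(-5, 5, -5, 5))
  expect_lt(lv["p"], 0.05)

  # hand evaluation: one-way ANOVA on |x - group mean|
  g1 <- c(1.0, 1.3, 0.9, 1.6); g2 <- c(1.0, 1.05, 0.95, 1.02)
  z1 <- abs(g1 - mean(g1)); z2 <- abs(g2 - mean(g2))
  z <- c(z1, z2); k <- 2; N <- 8
  ssb <- 4 * (mean(z1) - mean(z))^2 + 4 * (mean(z2) - mean(z))^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  W_hand <- (ssb / (k - 1)) / (ssw / (N - k))
  lv <- levene_test(g1, g2)
  expect_equal(unname(lv["W"]), W_hand, tolerance = 1e-10)
  expect_equal(unname(lv["p"]), pf(W_hand, 1, 6, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(levene_test(1, c(1, 2)), "at least 2")
})

test_that("two-sample t-tests reproduce the pooled formula and the Welch identity", {
  # identical groups
  tt <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tt["t"]), 0, tolerance = 1e-12)
  expect_equal(unname(tt["p"]), 1, tolerance = 1e-12)

  # hand-evaluated pooled t: t = 0.2 / sqrt(0.01 * 2/3), df = 4
  tt <- two_sample_t(c(1.1, 1.2, 1.3), c(0.9, 1.0, 1.1), welch = FALSE)
  expect_equal(unname(tt["t"]), 0.2 / sqrt(0.01 * 2 / 3), tolerance = 1e-10)
  expect_equal(unname(tt["df"]), 4)
  expect_equal(unname(tt["p"]),
               2 * pt(0.2 / sqrt(0.01 * 2 / 3), 4, lower.tail = FALSE),
               tolerance = 1e-10)

  # equal n and equal sample variances: Welch and Student coincide
  g1 <- c(1.0, 1.2, 1.4, 1.6); g2 <- g1 + 0.3
  a <- two_sample_t(g1, g2, welch = FALSE)
  b <- two_sample_t(g1, g2, welch = TRUE)
  expect_equal(unname(a["t"]), unname(b["t"]), tolerance = 1e-12)
  expect_equal(unname(a["df"]), unname(b["df"]), tolerance = 1e-9)

  # degenerate zero-variance contract
  tt <- two_sample_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(unname(tt[c("t", "p")]), c(0, 1))
})

test_that("Bonferroni multiplies by the fixed family size, capped at 1", {
  expect_equal(bonferroni(6.29e-7, 32), 2.0128e-5, tolerance = 1e-6)
  expect_equal(bonferroni(1.12e-5, 32), 3.584e-4, tolerance = 1e-6)
  expect_equal(bonferroni(0.003, 16), 0.048, tolerance = 1e-12)
  expect_equal(bonferroni(0.5, 3), 1.0)
  # agreement with p.adjust's bonferroni at the same family size
  p <- c(1e-6, 0.004, 0.2, 0.9)
  expect_equal(bonferroni(p, 32), p.adjust(p, "bonferroni", n = 32))
  # monotone in both arguments
  expect_true(all(diff(bonferroni(sort(p), 16)) >= 0))
  expect_lte(bonferroni(0.01, 8), bonferroni(0.01, 16))
})

test_that("cDNA-vs-gDNA contrast returns the null result on identical ratios", {
  samples <- tiny_samples()
  samples <- rbind(samples, data.frame(sample_id = "S5", tissue = "DLPFC",
                                       ch10_104957618_I = "D/I",
                                       rs3740387 = "C/T"))
  peaks <- tiny_peaks(ratio_cdna = 1)  # every cDNA ratio equals every gDNA ratio
  peaks <- rbind(peaks, transform(tiny_peaks(ratio_cdna = 1)[1:8, ],
                                  sample_id = "S5"))
  rs <- compute_ratio_summaries(peaks, samples)
  assay <- default_assays()[default_assays()$assay_id == "rs3740387", ]
  fit <- phase_assay(samples, "ch10_104957618_I", assay)
  calls <- orient_samples(samples, "ch10_104957618_I", assay, fit,
                          threshold = 0.5)
  row <- compare_cdna_vs_gdna(rs$summaries, samples, calls, assay, "DLPFC",
                              "ch10_104957618_I")
  expect_true(row$testable)
  expect_equal(row$percent_effect, 0, tolerance = 1e-9)
  expect_equal(row$t_stat, 0, tolerance = 1e-9)
  expect_equal(row$p_raw, 1)
  expect_equal(row$p_corrected, 1)
})

test_that("contrasts recover a simulated fold change and flag tiny groups", {
  cfg <- sim_config(n_per_tissue = c(fetal_whole_brain = 160),
                    fold_change = 1.4, noise_sd = 0.08, seed = 31)
  cohort <- simulate_cohort(cfg)
  rs <- compute_ratio_summaries(cohort$peaks, cohort$samples)
  assay <- default_assays()[default_assays()$assay_id == cfg$assay_id, ]
  fit <- phase_assay(cohort$samples, cfg$risk_locus, assay)
  calls <- orient_samples(cohort$samples, cfg$risk_locus, assay, fit)
  row <- compare_cdna_vs_gdna(rs$summaries, cohort$samples, calls, assay,
                              "fetal_whole_brain", cfg$risk_locus)
  expect_true(row$testable)
  expect_equal(row$mean_group1, 1.4, tolerance = 0.05)
  expect_equal(row$percent_effect, 40, tolerance = 5)
  expect_lt(row$p_corrected, 0.05)

  hv <- compare_het_vs_hom(rs$summaries, cohort$samples, calls, assay,
                           "fetal_whole_brain", cfg$risk_locus)
  # only the risk variant carries the cis-effect: homozygote ratios sit
  # near 1, heterozygotes near the fold change
  expect_true(hv$testable)
  expect_equal(hv$mean_group2, 1, tolerance = 0.05)
  expect_lt(hv$p_raw, 0.05)

  # a genotype group below the minimum size is flagged not-testable
  few <- cohort$samples$tissue == "fetal_whole_brain"
  sub <- cohort$samples
  keep_hom <- which(few & !is_het(sub$ch10_104957618_I))[1]
  drop <- which(few & !is_het(sub$ch10_104957618_I))
  drop <- setdiff(drop, keep_hom)
  sub <- sub[!seq_len(nrow(sub)) %in% drop, ]
  hv2 <- compare_het_vs_hom(rs$summaries, sub, calls, assay,
                            "fetal_whole_brain", cfg$risk_locus)
  expect_false(hv2$testable)
  expect_true(is.na(hv2$p_raw))
})
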