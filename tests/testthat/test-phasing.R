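test_that("genotype counts tabulate joint genotypes with missing data dropped", {
  s <- tiny_samples()
  cts <- two_locus_counts(s, "ch10_104957618_I", "rs3740387")
  # allele a1 = "I" (allele_ref), b1 = "C"; S4 has a missing expressed genotype
  expect_equal(sum(cts), 3)
  expect_equal(cts["a1a2", "b1b2"], 2L)  # S1, S2 double heterozygotes
  expect_equal(cts["a2a2", "b1b2"], 1L)  # S3
})

test_that("EM equals direct gamete counting when no double heterozygotes exist", {
  cts <- counts_matrix(c(10, 4, 0,
                         3, 0, 2,
                         0, 5, 6))
  fit <- em_haplotype_frequencies(cts)
  n <- sum(cts)
  # unambiguous gamete counts / 2N
  expected <- c(a1b1 = 2 * 10 + 4 + 3, a1b2 = 0 + 4 + 2,
                a2b1 = 0 + 5 + 3, a2b2 = 2 * 6 + 5 + 2) / (2 * n)
  expect_equal(fit$f, expected, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("EM finds the boundary MLE for a fully coupled table", {
  cts <- counts_matrix(c(30, 0, 0,
                         0, 40, 0,
                         0, 0, 30))
  fit <- em_haplotype_frequencies(cts)
  expect_equal(unname(fit$f), c(0.5, 0, 0, 0.5), tolerance = 1e-7)
  expect_equal(unname(fit$D_prime), 1, tolerance = 1e-6)
  expect_equal(unname(fit$r2), 1, tolerance = 1e-6)
  # grid oracle confirms the boundary maximum
  expect_gte(fit$loglik, grid_loglik_max(cts, step = 0.05) - 1e-6)
})

test_that("EM preserves margins, sums to 1, and has monotone log-likelihood", {
  set.seed(404)
  for (rep in 1:25) {
    cts <- counts_matrix(rmultinom(1, size = sample(5:60, 1), prob = runif(9)))
    d1 <- sum(c(2, 1, 0) * rowSums(cts)) / (2 * sum(cts))
    d2 <- sum(c(2, 1, 0) * colSums(cts)) / (2 * sum(cts))
    if (d1 %in% c(0, 1) || d2 %in% c(0, 1)) next
    fit <- em_haplotype_frequencies(cts, trace = TRUE)
    expect_equal(sum(fit$f), 1, tolerance = 1e-9)
    expect_equal(unname(fit$f["a1b1"] + fit$f["a1b2"]), d1, tolerance = 1e-6)
    expect_equal(unname(fit$f["a1b1"] + fit$f["a2b1"]), d2, tolerance = 1e-6)
    if (length(fit$loglik_trace) > 1) {
      expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    }
  }
})

test_that("EM likelihood matches the exhaustive grid oracle on small tables", {
  logP <- grid_logprob_matrix(step = 0.01)
  set.seed(77)
  # a spread of small tables incl. double-het-heavy ones
  tables <- c(
    lapply(1:40, function(i) counts_matrix(rmultinom(1, sample(2:20, 1),
                                                     prob = runif(9)))),
    list(counts_matrix(c(0, 0, 0, 0, 20, 0, 0, 0, 0)),
         counts_matrix(c(5, 0, 0, 0, 10, 0, 0, 0, 5)))
  )
  for (cts in tables) {
    d1 <- sum(c(2, 1, 0) * rowSums(cts)) / (2 * sum(cts))
    d2 <- sum(c(2, 1, 0) * colSums(cts)) / (2 * sum(cts))
    if (d1 %in% c(0, 1) || d2 %in% c(0, 1)) next
    fit <- em_haplotype_frequencies(cts)
    expect_gte(fit$loglik, grid_loglik_max_fast(cts, logP) - 1e-6)
  }
})

test_that("LD statistics evaluate their definitions", {
  # independence
  f <- c(0.6 * 0.3, 0.6 * 0.7, 0.4 * 0.3, 0.4 * 0.7)
  ld <- ld_statistics(f)
  expect_equal(unname(ld["D"]), 0, tolerance = 1e-12)
  expect_equal(unname(ld["r2"]), 0, tolerance = 1e-12)
  # complete coupling
  ld <- ld_statistics(c(0.5, 0, 0, 0.5))
  expect_equal(unname(ld["D"]), 0.25)
  expect_equal(unname(ld["D_prime"]), 1)
  expect_equal(unname(ld["r2"]), 1)
  # direct evaluation: D = 0.4 - 0.6*0.5 = 0.10, r2 = 0.01/(0.6*0.4*0.5*0.5)
  ld <- ld_statistics(c(0.4, 0.2, 0.1, 0.3))
  expect_equal(unname(ld["D"]), 0.10, tolerance = 1e-12)
  expect_equal(unname(ld["r2"]), 1 / 6, tolerance = 1e-12)
  expect_equal(unname(ld["D_prime"]), 0.5, tolerance = 1e-12)
  # r2 = 1 implies D' = 1 over random frequency draws; both lie in [0,1]
  set.seed(9)
  for (i in 1:50) {
    f <- as.vector(rmultinom(1, 1000, runif(4))) / 1000
    if (any(c(f[1] + f[2], f[1] + f[3]) %in% c(0, 1))) next
    ld <- ld_statistics(f)
    expect_true(ld["D_prime"] >= 0 && ld["D_prime"] <= 1 + 1e-12)
    expect_true(ld["r2"] >= 0 && ld["r2"] <= 1 + 1e-12)
    if (isTRUE(all.equal(unname(ld["r2"]), 1))) {
      expect_equal(unname(ld["D_prime"]), 1)
    }
  }
})

test_that("diplotype probabilities follow the two-diplotype frequency ratio", {
  expect_equal(diplotype_probability(0.3, 0.2, 0, 0.5), 1.0)
  expect_equal(diplotype_probability(0.25, 0.25, 0.25, 0.25), 0.5)
  expect_equal(diplotype_probability(0.6, 0.3, 0.05, 0.05),
               0.36 / (0.36 + 0.005), tolerance = 1e-12)
  expect_error(diplotype_probability(0.5, 0, 0, 0.5), "impossible")
  # complementarity: p(d1) + p(d2) = 1 for random valid frequencies
  set.seed(21)
  for (i in 1:50) {
    f <- runif(4)
    expect_equal(diplotype_probability(f[1], f[2], f[3], f[4]) +
                   diplotype_probability(f[3], f[4], f[1], f[2]), 1,
                 tolerance = 1e-12)
  }
})

test_that("orientation calls require double heterozygosity and a confident phase", {
  s <- tiny_samples()
  assay <- default_assays()[default_assays()$assay_id == "rs3740387", ]
  fit <- structure(list(f = c(a1b1 = 0.55, a1b2 = 0.34, a2b1 = 0.003,
                              a2b2 = 0.107)), class = "ase_hapfreq")
  # p(diplotype1) = .55*.107 / (.55*.107 + .34*.003) ~ 0.983
  calls <- orient_samples(s, "ch10_104957618_I", assay, fit, threshold = 0.94)
  expect_equal(calls$orientation[1:2], rep("risk_with_a1", 2))
  expect_true(all(calls$confident[1:2]))
  expect_true(is.na(calls$p_diplotype1[3]))   # risk homozygote: no call
  expect_true(is.na(calls$p_diplotype1[4]))   # missing expressed genotype
  # p = 0.5 is never confident above threshold 0.5
  fit$f <- c(a1b1 = 0.25, a1b2 = 0.25, a2b1 = 0.25, a2b2 = 0.25)
  calls <- orient_samples(s, "ch10_104957618_I", assay, fit, threshold = 0.51)
  expect_false(any(calls$confident))
})

test_that("Hardy-Weinberg chi-square matches hand calculation", {
  t1 <- hwe_test(25, 50, 25)
  expect_equal(unname(t1["chi2"]), 0, tolerance = 1e-12)
  expect_equal(unname(t1["p"]), 1)
  # expected counts 7.5/15/7.5 -> chi2 = 10/3
  t2 <- hwe_test(10, 10, 10)
  expect_equal(unname(t2["chi2"]), 10 / 3, tolerance = 1e-12)
  expect_equal(unname(t2["p"]),
               pchisq(10 / 3, 1, lower.tail = FALSE), tolerance = 1e-12)
  # monomorphic locus: undefined
  expect_true(all(is.na(hwe_test(0, 0, 50))))
})
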