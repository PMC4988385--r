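#' Levene's test for equality of variances between two groups
#'
#' Classic (mean-centered) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group mean, matching the SPSS
#' default. Median centering (Brown-Forsythe) is available via `center`.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return Named numeric `c(W, p)`. When every absolute deviation is zero
#'   in both groups the statistic is defined as `W = 0`, `p = 1`.
#' @examples
#' levene_test(c(1, 2, 3), c(4, 5, 6)) # identical spreads: W = 0, p = 1
#' @export
levene_test <- function(group1, group2, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  y <- c(group1, group2)
  g <- factor(rep(c("g1", "g2"), c(length(group1), length(group2))))
  centre_fun <- if (center == "mean") mean else stats::median
  z <- abs(y - stats::ave(y, g, FUN = centre_fun))
  if (all(z == 0) || stats::var(z) == 0) {
    return(c(W = 0, p = 1))
  }
  # near-zero residual variance in z makes the F-test warn; the huge W it
  # returns (variances maximally unequal) is the intended gate outcome
  lt <- suppressWarnings(car::leveneTest(y ~ g, center = centre_fun))
  W <- lt[1, "F value"]
  p <- lt[1, "Pr(>F)"]
  if (!is.finite(W)) { W <- 0; p <- 1 }
  c(W = unname(W), p = unname(p))
}

#' Two-sample t-test (pooled or Welch), two-tailed
#'
#' Thin wrapper over [stats::t.test()] adding the degenerate-data contract
#' needed in noise-free pipelines: when both groups have zero variance and
#' equal means the result is `t = 0, p = 1` rather than an error.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param welch If `TRUE`, Welch-Satterthwaite unequal-variance t-test;
#'   otherwise Student's pooled-variance test.
#' @return Named numeric `c(t, df, p)`; `p` is two-tailed.
#' @examples
#' two_sample_t(c(1.1, 1.2, 1.3), c(0.9, 1.0, 1.1), welch = FALSE)
#' @export
two_sample_t <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(group1) == 0 && stats::var(group2) == 0) {
    if (mean(group1) == mean(group2)) {
      df <- if (welch) NA_real_ else length(group1) + length(group2) - 2
      return(c(t = 0, df = df, p = 1))
    }
    return(c(t = if (mean(group1) > mean(group2)) Inf else -Inf,
             df = length(group1) + length(group2) - 2, p = 0))
  }
  tt <- stats::t.test(group1, group2, var.equal = !welch,
                      alternative = "two.sided")
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value))
}

#' Bonferroni correction with a fixed family size
#'
#' The family size is a design constant attached to the contrast family
#' (32 for the cDNA-vs-gDNA family: two risk variants x four genes x four
#' tissues; 16 for the heterozygote-vs-homozygote family: one variant x
#' four genes x four tissues), not recomputed from the number of contrasts
#' actually run.
#'
#' @param p_raw Raw P-value(s) in (0, 1].
#' @param m Family size (>= 1).
#' @return `min(1, p_raw * m)`, vectorised.
#' @examples
#' bonferroni(6.29e-7, 32) # 2.01e-5
#' bonferroni(0.003, 16)   # 0.048
#' @export
bonferroni <- function(p_raw, m) {
  # p = 0 arises only from the degenerate zero-variance contract
  stopifnot(m >= 1, all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  pmin(1, p_raw * m)
}

# Levene gate + t-test + effect summary shared by both contrasts.
#' @keywords internal
gated_comparison <- function(group1, group2, levene_alpha = 0.05,
                             min_group = 2L) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < min_group || n2 < min_group) {
    return(data.frame(mean_group1 = if (n1) mean(group1) else NA_real_,
                      mean_group2 = if (n2) mean(group2) else NA_real_,
                      n1 = n1, n2 = n2, levene_p = NA_real_,
                      welch_used = NA, t_stat = NA_real_, df = NA_real_,
                      p_raw = NA_real_, testable = FALSE))
  }
  lv <- levene_test(group1, group2)
  welch <- lv["p"] < levene_alpha
  tt <- two_sample_t(group1, group2, welch = welch)
  data.frame(mean_group1 = mean(group1), mean_group2 = mean(group2),
             n1 = n1, n2 = n2, levene_p = unname(lv["p"]),
             welch_used = unname(welch), t_stat = unname(tt["t"]),
             df = unname(tt["df"]), p_raw = unname(tt["p"]),
             testable = TRUE)
}

# Oriented per-sample mean ratios for one assay/tissue/template among the
# given sample ids. If the phase call is risk_with_a2 the assay numerator
# tags the non-risk chromosome, so the summary-level ratio is inverted.
#' @keywords internal
oriented_means <- function(summaries, ids, assay_id, template, flip) {
  sel <- summaries$assay_id == assay_id & summaries$template == template &
    summaries$sample_id %in% ids & summaries$usable & summaries$qc_pass
  m <- summaries$mean_ratio[sel]
  if (flip) m <- 1 / m
  stats::setNames(m, summaries$sample_id[sel])
}

#' Contrast: cDNA allele ratios in risk-variant heterozygotes vs genomic DNA
#'
#' Tests whether the risk allele is associated with a general increase or
#' decrease in allelic expression. Group 1 holds per-sample mean corrected
#' cDNA ratios of samples heterozygous at both the risk variant and the
#' expressed SNP (confidently phased); group 2 holds the same samples'
#' mean corrected gDNA ratios (the physical 1:1 standard). Variances are
#' compared by Levene's test at `levene_alpha`; an unequal-variance
#' (Welch) t-test is used where they differ, a pooled t-test otherwise.
#' Two-tailed throughout.
#'
#' @param summaries Ratio summaries from [compute_ratio_summaries()].
#' @param samples Sample table.
#' @param calls Phase calls from [orient_samples()].
#' @param assay One-row assay definition.
#' @param tissue Tissue label.
#' @param risk_locus Risk locus id.
#' @param m_tests Bonferroni family size (default 32).
#' @param levene_alpha Variance-gate significance level (default 0.05).
#' @param min_group Minimum group size to emit a P-value (default 2).
#' @param loci Locus table.
#' @return One-row `data.frame` (a results-table row): group means, sizes,
#'   Levene gate, t, df, raw and Bonferroni-corrected P, percent effect
#'   (from the cDNA group mean), and a `testable` flag.
#' @export
compare_cdna_vs_gdna <- function(summaries, samples, calls, assay, tissue,
                                 risk_locus, m_tests = 32L,
                                 levene_alpha = 0.05, min_group = 2L,
                                 loci = study_loci()) {
  in_tissue <- samples$sample_id[samples$tissue == tissue]
  het_r <- is_het(samples[[risk_locus]])
  het_r_ids <- samples$sample_id[!is.na(het_r) & het_r]
  conf <- calls$sample_id[calls$confident]
  ids <- Reduce(intersect, list(in_tissue, het_r_ids, conf))
  flip <- length(ids) > 0 &&
    any(calls$orientation[calls$sample_id %in% ids] == "risk_with_a2")
  cdna <- oriented_means(summaries, ids, assay$assay_id, "cDNA", flip)
  gdna <- oriented_means(summaries, names(cdna), assay$assay_id, "gDNA", flip)
  cdna <- cdna[names(cdna) %in% names(gdna)]
  res <- gated_comparison(unname(cdna), unname(gdna),
                          levene_alpha = levene_alpha, min_group = min_group)
  cbind(data.frame(gene = assay$gene, assay_id = assay$assay_id,
                   tissue = tissue, risk_locus = risk_locus,
                   contrast = "cdna_vs_gdna", stringsAsFactors = FALSE),
        res,
        data.frame(m_tests = m_tests,
                   p_corrected = if (is.na(res$p_raw)) NA_real_ else
                     bonferroni(res$p_raw, m_tests),
                   percent_effect = if (is.na(res$mean_group1)) NA_real_ else
                     percent_effect(res$mean_group1)))
}

#' Contrast: cDNA allele ratios in risk-variant heterozygotes vs homozygotes
#'
#' Tests whether genotype at the risk variant can directly account for
#' altered cis-regulation: cis-effects of the variant differ between the
#' two chromosomes of a heterozygote but are equal in a homozygote.
#' Group 1 holds mean corrected cDNA ratios of confidently phased double
#' heterozygotes; group 2 those of samples heterozygous at the expressed
#' SNP but homozygous (either allele) at the risk variant. Gating,
#' testing and correction as in [compare_cdna_vs_gdna()] with family size
#' 16.
#'
#' @inheritParams compare_cdna_vs_gdna
#' @param m_tests Bonferroni family size (default 16).
#' @return One-row results `data.frame` (`contrast = "het_vs_hom"`).
#'   `percent_effect` is reported from the heterozygote group mean.
#' @export
compare_het_vs_hom <- function(summaries, samples, calls, assay, tissue,
                               risk_locus, m_tests = 16L,
                               levene_alpha = 0.05, min_group = 2L,
                               loci = study_loci()) {
  in_tissue <- samples$sample_id[samples$tissue == tissue]
  het_r <- is_het(samples[[risk_locus]])
  het_ids <- intersect(samples$sample_id[!is.na(het_r) & het_r],
                       calls$sample_id[calls$confident])
  het_ids <- intersect(het_ids, in_tissue)
  hom_ids <- intersect(samples$sample_id[!is.na(het_r) & !het_r], in_tissue)
  flip <- length(het_ids) > 0 &&
    any(calls$orientation[calls$sample_id %in% het_ids] == "risk_with_a2")
  g1 <- oriented_means(summaries, het_ids, assay$assay_id, "cDNA", flip)
  g2 <- oriented_means(summaries, hom_ids, assay$assay_id, "cDNA", flip)
  res <- gated_comparison(unname(g1), unname(g2),
                          levene_alpha = levene_alpha, min_group = min_group)
  cbind(data.frame(gene = assay$gene, assay_id = assay$assay_id,
                   tissue = tissue, risk_locus = risk_locus,
                   contrast = "het_vs_hom", stringsAsFactors = FALSE),
        res,
        data.frame(m_tests = m_tests,
                   p_corrected = if (is.na(res$p_raw)) NA_real_ else
                     bonferroni(res$p_raw, m_tests),
                   percent_effect = if (is.na(res$mean_group1)) NA_real_ else
                     percent_effect(res$mean_group1)))
}
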