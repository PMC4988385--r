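#' Build a run configuration
#'
#' Consolidates the analysis constants: QC threshold on the replicate
#' coefficient of variation, phase-confidence cutoff, Levene gate level,
#' and the fixed Bonferroni family sizes for the two contrast families.
#'
#' @param samples_path,peaks_path Input table paths (may be `NULL` when
#'   tables are passed to [run_pipeline()] directly).
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param assays Assay definition table ([default_assays()] by default);
#'   only assays with peak data are analysed.
#' @param risk_loci Risk locus ids (default: the two study risk variants).
#' @param qc_cv_threshold Replicate-reproducibility cutoff (default 0.25).
#' @param phase_confidence_threshold Minimum diplotype probability for a
#'   confident orientation (default 0.90).
#' @param levene_alpha Variance-gate level (default 0.05).
#' @param bonferroni_cdna_vs_gdna,bonferroni_het_vs_hom Family sizes
#'   (defaults 32 and 16).
#' @param min_group Minimum group size for a testable contrast (default 2;
#'   a warning is attached to testable groups smaller than 5).
#' @param loci Locus table.
#' @return List of class `"ase_run_config"`.
#' @export
run_config <- function(samples_path = NULL, peaks_path = NULL, out_dir = NULL,
                       assays = default_assays(),
                       risk_loci = c("rs11191419", "ch10_104957618_I"),
                       qc_cv_threshold = 0.25,
                       phase_confidence_threshold = 0.90,
                       levene_alpha = 0.05,
                       bonferroni_cdna_vs_gdna = 32L,
                       bonferroni_het_vs_hom = 16L,
                       min_group = 2L,
                       loci = study_loci()) {
  stopifnot(qc_cv_threshold > 0, qc_cv_threshold <= 1,
            phase_confidence_threshold > 0, phase_confidence_threshold <= 1,
            levene_alpha > 0, levene_alpha <= 1,
            bonferroni_cdna_vs_gdna >= 1, bonferroni_het_vs_hom >= 1)
  structure(list(samples_path = samples_path, peaks_path = peaks_path,
                 out_dir = out_dir, assays = assays, risk_loci = risk_loci,
                 qc_cv_threshold = qc_cv_threshold,
                 phase_confidence_threshold = phase_confidence_threshold,
                 levene_alpha = levene_alpha,
                 bonferroni_cdna_vs_gdna = as.integer(bonferroni_cdna_vs_gdna),
                 bonferroni_het_vs_hom = as.integer(bonferroni_het_vs_hom),
                 min_group = as.integer(min_group), loci = loci),
            class = "ase_run_config")
}

#' Run the full allele-specific expression analysis
#'
#' Executes the stages in order: read (or accept) the sample and peak
#' tables; Hardy-Weinberg screen; replicate ratios with per plate x assay
#' genomic-DNA correction and QC; EM phasing and orientation per
#' (risk locus, assay) pair on the pooled cohort; both contrast families
#' per gene x tissue x risk locus with the Levene gate and fixed
#' Bonferroni families; write `results.tsv`, `ratios.tsv`, `phase.tsv`
#' and a run log when `out_dir` is set.
#'
#' @param config An [run_config()] object.
#' @param samples,peaks Optional in-memory tables overriding the
#'   configured paths.
#' @return List: `results` (one row per gene x tissue x risk locus x
#'   contrast), `summaries`, `corrections`, `phase` (per-pair haplotype
#'   frequencies and LD), `calls`, `hwe`, `log`.
#' @export
run_pipeline <- function(config, samples = NULL, peaks = NULL) {
  stopifnot(inherits(config, "ase_run_config"))
  log <- character(0)
  if (is.null(samples)) {
    if (is.null(config$samples_path)) stop("no sample table given", call. = FALSE)
    samples <- read_samples(config$samples_path, loci = config$loci)
  }
  if (is.null(peaks)) {
    if (is.null(config$peaks_path)) stop("no peaks table given", call. = FALSE)
    peaks <- read_peaks(config$peaks_path)
  }
  log <- c(log, sprintf("read %d samples, %d peak rows", nrow(samples),
                        nrow(peaks)))

  hwe <- hwe_screen(samples, loci = config$loci)
  dev <- hwe$locus_id[!is.na(hwe$p) & hwe$p < 0.05]
  if (length(dev)) {
    log <- c(log, paste("Hardy-Weinberg deviation (p < 0.05) at:",
                        paste(dev, collapse = ", ")))
  }

  rat <- compute_ratio_summaries(peaks, samples,
                                 cv_threshold = config$qc_cv_threshold)
  log <- c(log, rat$log)

  assays <- config$assays[config$assays$assay_id %in% peaks$assay_id, ,
                          drop = FALSE]
  if (!nrow(assays)) stop("no configured assay has peak data", call. = FALSE)
  tissues <- unique(samples$tissue)
  risk_loci <- intersect(config$risk_loci, names(samples))

  phase_rows <- list(); call_rows <- list(); res_rows <- list()
  for (ri in risk_loci) {
    for (ai in seq_len(nrow(assays))) {
      assay <- assays[ai, , drop = FALSE]
      fit <- phase_assay(samples, ri, assay, loci = config$loci)
      phase_rows[[paste(ri, assay$assay_id)]] <- data.frame(
        risk_locus = ri, assay_id = assay$assay_id,
        f_risk_a1 = unname(fit$f["a1b1"]), f_risk_a2 = unname(fit$f["a1b2"]),
        f_nonrisk_a1 = unname(fit$f["a2b1"]),
        f_nonrisk_a2 = unname(fit$f["a2b2"]),
        D = unname(fit$D), D_prime = unname(fit$D_prime), r2 = unname(fit$r2),
        n_iter = fit$n_iter, stringsAsFactors = FALSE)
      calls <- orient_samples(samples, ri, assay, fit,
                              threshold = config$phase_confidence_threshold,
                              loci = config$loci)
      n_unconf <- sum(!is.na(calls$p_diplotype1) & !calls$confident)
      if (n_unconf) {
        log <- c(log, sprintf(
          "%s x %s: %d double heterozygotes below phase confidence %.2f",
          ri, assay$assay_id, n_unconf, config$phase_confidence_threshold))
      }
      call_rows[[paste(ri, assay$assay_id)]] <-
        cbind(risk_locus = ri, assay_id = assay$assay_id, calls)
      for (ti in tissues) {
        r1 <- compare_cdna_vs_gdna(rat$summaries, samples, calls, assay, ti,
                                   ri, m_tests = config$bonferroni_cdna_vs_gdna,
                                   levene_alpha = config$levene_alpha,
                                   min_group = config$min_group,
                                   loci = config$loci)
        r2 <- compare_het_vs_hom(rat$summaries, samples, calls, assay, ti,
                                 ri, m_tests = config$bonferroni_het_vs_hom,
                                 levene_alpha = config$levene_alpha,
                                 min_group = config$min_group,
                                 loci = config$loci)
        res_rows[[length(res_rows) + 1L]] <- rbind(r1, r2)
        for (rr in list(r1, r2)) {
          if (isTRUE(rr$testable) && min(rr$n1, rr$n2) < 5) {
            log <- c(log, sprintf(
              "%s %s %s %s: testable but a group has n < 5 (n1=%d, n2=%d)",
              rr$gene, ti, ri, rr$contrast, rr$n1, rr$n2))
          }
          if (isFALSE(rr$testable)) {
            log <- c(log, sprintf(
              "%s %s %s %s: not testable (n1=%d, n2=%d)",
              rr$gene, ti, ri, rr$contrast, rr$n1, rr$n2))
          }
        }
      }
    }
  }
  results <- do.call(rbind, res_rows)
  rownames(results) <- NULL
  phase <- do.call(rbind, phase_rows)
  rownames(phase) <- NULL
  calls <- do.call(rbind, call_rows)
  rownames(calls) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(results, file.path(config$out_dir, "results.tsv"))
    utils::write.table(format_ratios(rat$summaries),
                       file.path(config$out_dir, "ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(phase, file.path(config$out_dir, "phase.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  list(results = results, summaries = rat$summaries,
       corrections = rat$corrections, phase = phase, calls = calls,
       hwe = hwe, log = log)
}

#' @keywords internal
format_ratios <- function(summaries) {
  out <- summaries
  for (j in c("mean_ratio", "sd_ratio", "cv")) {
    out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.4f", out[[j]]))
  }
  out
}
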