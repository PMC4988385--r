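#' Simulation configuration for a synthetic ASE cohort
#'
#' Defines the generative model of one risk variant and one expressed tag
#' SNP. Samples receive two haplotypes drawn i.i.d. from
#' `haplotype_freqs` (Hardy-Weinberg at the diplotype level). Peak heights
#' start from `baseline_signal` fluorescence units per chromosome; the
#' allele-1 signal is multiplied by `assay_bias` in both templates
#' (assay-specific allelic bias, exactly the confound the genomic-DNA
#' plate correction removes); in cDNA only, the expressed allele carried
#' on each risk-bearing chromosome is additionally multiplied by the
#' allelic fold change `fold_change` (1 = null); every peak then receives
#' independent log-normal noise with log-scale SD `noise_sd`.
#'
#' @param n_per_tissue Named integer vector of cohort sizes. Defaults
#'   mirror the study scale: 40/38/38 adult samples across three brain
#'   regions plus 95 fetal samples.
#' @param haplotype_freqs Four frequencies, order (risk-a1, risk-a2,
#'   nonrisk-a1, nonrisk-a2), summing to 1. The default gives a
#'   risk-allele frequency of 0.90, an expressed-allele (a1) frequency of
#'   0.55 and a double-heterozygote phase probability of about 0.99,
#'   matching the strong regional linkage disequilibrium the assay design
#'   relies on.
#' @param fold_change Allelic fold change of the risk-bearing chromosome
#'   in cDNA (default 0.85, a 15% reduction).
#' @param assay_bias Allele-1 signal multiplier shared by gDNA and cDNA
#'   (default 1.2).
#' @param noise_sd Log-scale SD of per-peak multiplicative noise
#'   (default 0.1).
#' @param baseline_signal Per-chromosome fluorescence baseline
#'   (default 2000).
#' @param n_replicates Technical replicates per template per sample
#'   (default 4).
#' @param n_plates Number of assay plates samples are spread across
#'   (default 3).
#' @param risk_locus,assay_id,gene Identity of the simulated pair
#'   (defaults: the upstream indel risk variant tagging NT5C2).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `"ase_sim_config"`.
#' @export
sim_config <- function(n_per_tissue = c(DLPFC = 40, hippocampus = 38,
                                        caudate = 38, fetal_whole_brain = 95),
                       haplotype_freqs = c(0.55, 0.35, 0.002, 0.098),
                       fold_change = 0.85,
                       assay_bias = 1.2,
                       noise_sd = 0.1,
                       baseline_signal = 2000,
                       n_replicates = 4L,
                       n_plates = 3L,
                       risk_locus = "ch10_104957618_I",
                       assay_id = "rs3740387",
                       gene = "NT5C2",
                       seed = 1L) {
  stopifnot(length(haplotype_freqs) == 4, all(haplotype_freqs >= 0),
            abs(sum(haplotype_freqs) - 1) < 1e-8,
            fold_change > 0, noise_sd >= 0, baseline_signal > 0,
            n_replicates >= 1, n_plates >= 1, all(n_per_tissue >= 1))
  p_risk <- haplotype_freqs[1] + haplotype_freqs[2]
  p_a1 <- haplotype_freqs[1] + haplotype_freqs[3]
  if (p_risk %in% c(0, 1) || p_a1 %in% c(0, 1)) {
    stop("degenerate haplotype frequencies: a locus is monomorphic",
         call. = FALSE)
  }
  structure(list(n_per_tissue = n_per_tissue,
                 haplotype_freqs = haplotype_freqs,
                 fold_change = fold_change, assay_bias = assay_bias,
                 noise_sd = noise_sd, baseline_signal = baseline_signal,
                 n_replicates = as.integer(n_replicates),
                 n_plates = as.integer(n_plates),
                 risk_locus = risk_locus, assay_id = assay_id, gene = gene,
                 seed = as.integer(seed)),
            class = "ase_sim_config")
}

# Run fn with the RNG seeded locally; the caller's RNG state is untouched.
#' @keywords internal
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Simulate a synthetic cohort of genotypes and peak heights
#'
#' Generates a sample table and a peak-height table in exactly the
#' schemas the readers and the pipeline consume, together with the ground
#' truth used for parameter-recovery tests. Peaks are emitted only for
#' samples heterozygous at the expressed SNP (the informative samples the
#' assay design measures). Homozygotes at the expressed SNP appear in the
#' sample table with genotypes only.
#'
#' @param config An [sim_config()] object.
#' @return List with `samples`, `peaks`, `truth`. `truth` has one row per
#'   sample: haplotype pair, `true_cdna_ratio` (the bias-free corrected
#'   cDNA ratio implied by the diplotype: `fold_change` when the risk
#'   allele is in cis with allele a1, its reciprocal when in cis with a2,
#'   1 in risk homozygotes) plus the per-plate correction target
#'   (`assay_bias`) as attribute `"correction_target"`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_tissue = c(DLPFC = 8), seed = 7))
#' head(cohort$peaks)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ase_sim_config"))
  with_local_seed(config$seed, function() simulate_cohort_impl(config))
}

#' @keywords internal
simulate_cohort_impl <- function(cfg) {
  loci <- study_loci()
  rl <- locus_row(loci, cfg$risk_locus)
  assays <- default_assays()
  assay <- assays[assays$assay_id == cfg$assay_id, , drop = FALSE]
  if (!nrow(assay)) stop("unknown assay '", cfg$assay_id, "'", call. = FALSE)
  risk <- rl$risk_allele
  nonrisk <- setdiff(c(rl$allele_ref, rl$allele_alt), risk)
  # haplotypes: 1 = risk/a1, 2 = risk/a2, 3 = nonrisk/a1, 4 = nonrisk/a2
  hap_risk <- c(risk, risk, nonrisk, nonrisk)
  hap_expr <- c(assay$allele_a1, assay$allele_a2,
                assay$allele_a1, assay$allele_a2)

  tissues <- rep(names(cfg$n_per_tissue), cfg$n_per_tissue)
  n <- length(tissues)
  sample_id <- sprintf("S%04d", seq_len(n))
  h1 <- sample.int(4, n, replace = TRUE, prob = cfg$haplotype_freqs)
  h2 <- sample.int(4, n, replace = TRUE, prob = cfg$haplotype_freqs)

  gt_risk <- vapply(seq_len(n), function(i)
    paste(sort(c(hap_risk[h1[i]], hap_risk[h2[i]])), collapse = "/"),
    character(1))
  gt_expr <- vapply(seq_len(n), function(i)
    paste(sort(c(hap_expr[h1[i]], hap_expr[h2[i]])), collapse = "/"),
    character(1))
  samples <- data.frame(sample_id = sample_id, tissue = tissues,
                        stringsAsFactors = FALSE)
  samples[[cfg$risk_locus]] <- gt_risk
  samples[[cfg$assay_id]] <- gt_expr

  # true cDNA allelic ratio implied by the diplotype (a1-signal over
  # a2-signal, before assay bias): risk chromosome multiplied by rho
  rho <- cfg$fold_change
  chrom_rho <- function(h) ifelse(hap_risk[h] == risk, rho, 1)
  true_ratio <- rep(NA_real_, n)
  informative <- hap_expr[h1] != hap_expr[h2]
  a1_first <- hap_expr[h1] == assay$allele_a1
  r1 <- chrom_rho(h1); r2 <- chrom_rho(h2)
  true_ratio[informative & a1_first] <-
    (r1 / r2)[informative & a1_first]
  true_ratio[informative & !a1_first] <-
    (r2 / r1)[informative & !a1_first]
  truth <- data.frame(sample_id = sample_id, tissue = tissues,
                      hap1 = h1, hap2 = h2,
                      true_cdna_ratio = true_ratio,
                      stringsAsFactors = FALSE)
  attr(truth, "correction_target") <- cfg$assay_bias

  plate <- sprintf("P%02d", (seq_len(n) - 1L) %% cfg$n_plates + 1L)
  inf_idx <- which(informative)
  if (!length(inf_idx)) {
    stop("no samples heterozygous at the expressed SNP were generated",
         call. = FALSE)
  }
  nrep <- cfg$n_replicates
  nblk <- length(inf_idx) * nrep
  noise <- function() if (cfg$noise_sd > 0)
    exp(stats::rnorm(nblk, 0, cfg$noise_sd)) else rep(1, nblk)

  # per-chromosome contribution to each allele peak; heterozygotes have
  # one chromosome per allele, so each peak is a single chromosome's signal
  rho_a1 <- ifelse(a1_first[inf_idx], r1[inf_idx], r2[inf_idx])
  rho_a2 <- ifelse(a1_first[inf_idx], r2[inf_idx], r1[inf_idx])
  base <- cfg$baseline_signal
  idx <- rep(inf_idx, each = nrep)
  mk <- function(template) {
    a1_mean <- base * cfg$assay_bias *
      (if (template == "cDNA") rep(rho_a1, each = nrep) else 1)
    a2_mean <- base * (if (template == "cDNA") rep(rho_a2, each = nrep) else 1)
    data.frame(plate_id = plate[idx], sample_id = sample_id[idx],
               assay_id = cfg$assay_id, template = template,
               replicate = rep(seq_len(nrep), times = length(inf_idx)),
               peak_a1 = a1_mean * noise(), peak_a2 = a2_mean * noise(),
               stringsAsFactors = FALSE)
  }
  peaks <- rbind(mk("gDNA"), mk("cDNA"))
  list(samples = samples, peaks = peaks, truth = truth)
}

#' Monte-Carlo recovery and calibration experiment
#'
#' Repeatedly simulates a cohort and runs the full analysis chain
#' (ratio stage, EM phasing, orientation, and the cDNA-vs-gDNA contrast),
#' summarising how well the allelic fold change is recovered and how often
#' the contrast rejects at `alpha`. Under the null (`fold_change = 1`)
#' the rejection rate estimates the type-I error of the whole pipeline.
#'
#' @param config An [sim_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param n_reps Number of simulated cohorts.
#' @param alpha Nominal significance level (default 0.05).
#' @param tissue Tissue whose contrast is evaluated (default: first entry
#'   of `config$n_per_tissue`).
#' @return List: `estimates` (per-rep mean corrected double-heterozygote
#'   cDNA ratio), `p_values`, `mean_estimate`, `sd_estimate`,
#'   `rejection_rate`, `n_reps`, `true_fold_change`.
#' @export
recovery_experiment <- function(config, n_reps, alpha = 0.05,
                                tissue = names(config$n_per_tissue)[1]) {
  stopifnot(n_reps >= 1)
  est <- p <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    res <- tryCatch(analyze_one_cohort(cfg, tissue), error = function(e) NULL)
    if (!is.null(res)) { est[r] <- res$estimate; p[r] <- res$p }
  }
  ok <- !is.na(p)
  list(estimates = est, p_values = p,
       mean_estimate = mean(est[ok]), sd_estimate = stats::sd(est[ok]),
       rejection_rate = mean(p[ok] < alpha), n_reps = n_reps,
       n_used = sum(ok), true_fold_change = config$fold_change)
}

# One simulate -> ratios -> phase -> contrast pass; returns the estimated
# double-heterozygote cDNA mean ratio and the contrast's raw P.
#' @keywords internal
analyze_one_cohort <- function(cfg, tissue) {
  cohort <- simulate_cohort(cfg)
  rs <- compute_ratio_summaries(cohort$peaks, cohort$samples)
  assays <- default_assays()
  assay <- assays[assays$assay_id == cfg$assay_id, , drop = FALSE]
  fit <- phase_assay(cohort$samples, cfg$risk_locus, assay)
  calls <- orient_samples(cohort$samples, cfg$risk_locus, assay, fit)
  row <- compare_cdna_vs_gdna(rs$summaries, cohort$samples, calls, assay,
                              tissue, cfg$risk_locus)
  list(estimate = row$mean_group1, p = row$p_raw, row = row)
}
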