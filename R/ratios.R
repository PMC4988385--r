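#' Raw allelic ratio from two peak heights
#'
#' The raw ratio for one replicate is the peak height of the expressed
#' allele generally in phase with the risk alleles (`peak_a1`) divided by
#' the peak height of the allele generally in phase with the non-risk
#' alleles (`peak_a2`). Replicates with a zero or negative peak are
#' invalid: the ratio is `NA` and the replicate is excluded from summaries.
#'
#' @param peak_a1,peak_a2 Numeric vectors of fluorescence peak heights.
#' @return Numeric vector of ratios; `NA` where either peak is not
#'   strictly positive.
#' @examples
#' raw_ratio(1200, 1000) # 1.2
#' raw_ratio(500, 0)     # NA (invalid replicate)
#' @export
raw_ratio <- function(peak_a1, peak_a2) {
  out <- peak_a1 / peak_a2
  out[!is.finite(peak_a1) | !is.finite(peak_a2) |
        peak_a1 <= 0 | peak_a2 <= 0] <- NA_real_
  out
}

#' Plate correction factor from genomic-DNA ratios
#'
#' Genomic DNA from a heterozygote carries exactly one copy of each allele,
#' so its allelic ratio is a physical 1:1 standard. The mean raw gDNA
#' ratio on a plate therefore measures the assay-specific allelic signal
#' bias, and dividing every ratio on that plate by it removes the bias.
#'
#' @param gdna_raw_ratios Raw gDNA ratios (heterozygous samples only) from
#'   one plate and one assay; `NA`s (invalid replicates) are dropped.
#' @param plate_id,assay_id Identifiers recorded in the result.
#' @return A one-row `data.frame`: `plate_id`, `assay_id`,
#'   `correction_factor`, `n_gdna`.
#' @export
plate_correction_factor <- function(gdna_raw_ratios, plate_id = NA_character_,
                                    assay_id = NA_character_) {
  r <- gdna_raw_ratios[is.finite(gdna_raw_ratios)]
  if (!length(r)) {
    stop("no valid gDNA ratios on plate '", plate_id, "' for assay '",
         assay_id, "': plate unanalyzable", call. = FALSE)
  }
  data.frame(plate_id = plate_id, assay_id = assay_id,
             correction_factor = mean(r), n_gdna = length(r),
             stringsAsFactors = FALSE)
}

#' Correct a raw ratio by its plate factor
#' @param raw Raw ratio(s).
#' @param correction_factor Positive scalar from [plate_correction_factor()]
#'   (or the one-row data frame itself).
#' @return Corrected ratio(s) `raw / correction_factor`.
#' @export
corrected_ratio <- function(raw, correction_factor) {
  if (is.data.frame(correction_factor)) {
    correction_factor <- correction_factor$correction_factor
  }
  stopifnot(is.numeric(correction_factor), correction_factor > 0)
  raw / correction_factor
}

#' Summarise replicate ratios for one sample, assay and template
#'
#' Computes the replicate mean, sample standard deviation (n-1
#' denominator) and coefficient of variation, and applies the
#' reproducibility filter: cDNA summaries with CV (= sd/mean) above
#' `cv_threshold` fail QC and are excluded from statistical comparisons.
#' The filter applies to cDNA only; gDNA always passes.
#'
#' @param ratios Corrected replicate ratios (invalid replicates as `NA`).
#' @param template `"gDNA"` or `"cDNA"`.
#' @param cv_threshold QC cutoff on sd/mean for cDNA (default 0.25).
#' @param min_replicates Minimum number of valid replicates for a usable
#'   summary (default 2; a mean and SD need at least two points).
#' @return One-row `data.frame` with `mean_ratio`, `sd_ratio`, `cv`,
#'   `n_replicates`, `qc_pass`, `usable`. When fewer than `min_replicates`
#'   replicates are valid, `usable` is `FALSE` and the moments are `NA`.
#' @examples
#' summarize_replicates(c(1.0, 1.5, 0.5, 1.0), "cDNA") # cv ~ 0.41, fails QC
#' @export
summarize_replicates <- function(ratios, template = c("cDNA", "gDNA"),
                                 cv_threshold = 0.25, min_replicates = 2L) {
  template <- match.arg(template)
  r <- ratios[is.finite(ratios)]
  n <- length(r)
  if (n < min_replicates) {
    return(data.frame(mean_ratio = NA_real_, sd_ratio = NA_real_,
                      cv = NA_real_, n_replicates = n, qc_pass = FALSE,
                      usable = FALSE))
  }
  m <- mean(r)
  s <- stats::sd(r)
  cv <- s / m
  qc <- if (template == "cDNA") cv <= cv_threshold else TRUE
  data.frame(mean_ratio = m, sd_ratio = s, cv = cv, n_replicates = n,
             qc_pass = qc, usable = TRUE)
}

#' Percent allelic-expression effect from a mean corrected ratio
#'
#' Expresses the deviation of a mean corrected cDNA ratio from the 1:1
#' genomic ratio as a percentage. Negative values are reductions of the
#' risk-phase allele (a ratio of 0.85 is a 15% reduction), positive values
#' increases.
#'
#' @param mean_ratio Positive mean corrected ratio(s).
#' @return `(mean_ratio - 1) * 100`.
#' @examples
#' percent_effect(0.85) # -15
#' percent_effect(1.4)  # +40
#' @export
percent_effect <- function(mean_ratio) {
  stopifnot(all(mean_ratio > 0, na.rm = TRUE))
  (mean_ratio - 1) * 100
}

#' Full ratio stage: peaks to per-sample ratio summaries
#'
#' Runs the complete measurement-processing chain for every assay: raw
#' replicate ratios, per plate x assay correction factors from
#' heterozygote gDNA, corrected ratios, and per sample x assay x template
#' summaries with QC.
#'
#' @param peaks Peak table as from [read_peaks()].
#' @param samples Sample table as from [read_samples()]; used to restrict
#'   correction factors and summaries to samples heterozygous at each
#'   assay's expressed SNP (only heterozygote gDNA embodies the 1:1
#'   assumption, and only heterozygotes are informative for allele-specific
#'   expression).
#' @param cv_threshold,min_replicates Passed to [summarize_replicates()].
#' @return A list with elements `summaries` (one row per sample x assay x
#'   template with the [summarize_replicates()] columns), `corrections`
#'   (one row per plate x assay) and `log` (character vector describing
#'   exclusions).
#' @export
compute_ratio_summaries <- function(peaks, samples, cv_threshold = 0.25,
                                    min_replicates = 2L) {
  log <- character(0)
  # restrict to samples heterozygous at the assay SNP
  het_ok <- logical(nrow(peaks))
  si <- match(peaks$sample_id, samples$sample_id)
  for (aid in unique(peaks$assay_id)) {
    rows <- peaks$assay_id == aid
    if (!aid %in% names(samples)) next
    het_ok[rows] <- !is.na(si[rows]) &
      vapply(is_het(samples[[aid]][si[rows]]), isTRUE, logical(1))
  }
  n_drop <- sum(!het_ok)
  if (n_drop) {
    log <- c(log, sprintf(
      "dropped %d peak rows from samples not heterozygous at the assay SNP",
      n_drop))
  }
  pk <- peaks[het_ok, , drop = FALSE]
  if (!nrow(pk)) stop("no peak rows from informative heterozygotes", call. = FALSE)
  pk$raw <- raw_ratio(pk$peak_a1, pk$peak_a2)
  n_invalid <- sum(is.na(pk$raw))
  if (n_invalid) {
    log <- c(log, sprintf("%d replicates invalid (non-positive peak)", n_invalid))
  }

  # per plate x assay correction factors from gDNA raw ratios
  gd <- pk[pk$template == "gDNA", , drop = FALSE]
  corr_key <- unique(pk[, c("plate_id", "assay_id")])
  corrections <- do.call(rbind, lapply(seq_len(nrow(corr_key)), function(i) {
    sel <- gd$plate_id == corr_key$plate_id[i] &
      gd$assay_id == corr_key$assay_id[i]
    plate_correction_factor(gd$raw[sel], corr_key$plate_id[i],
                            corr_key$assay_id[i])
  }))

  ci <- match(paste(pk$plate_id, pk$assay_id),
              paste(corrections$plate_id, corrections$assay_id))
  pk$corrected <- pk$raw / corrections$correction_factor[ci]

  # grouped replicate summaries (vectorised equivalent of
  # summarize_replicates() per sample x assay x template)
  grp <- paste(pk$sample_id, pk$assay_id, pk$template, sep = "\r")
  valid <- is.finite(pk$corrected)
  x <- ifelse(valid, pk$corrected, 0)
  levs <- unique(grp)
  gi <- match(grp, levs)
  n_v <- as.vector(rowsum(as.numeric(valid), gi))
  sx <- as.vector(rowsum(x, gi))
  sxx <- as.vector(rowsum(x^2, gi))
  m <- ifelse(n_v > 0, sx / n_v, NA_real_)
  s2 <- ifelse(n_v > 1, pmax(0, (sxx - n_v * m^2) / (n_v - 1)), NA_real_)
  first <- match(levs, grp)
  summaries <- data.frame(
    sample_id = pk$sample_id[first], assay_id = pk$assay_id[first],
    template = pk$template[first], mean_ratio = m, sd_ratio = sqrt(s2),
    cv = sqrt(s2) / m, n_replicates = as.integer(n_v),
    stringsAsFactors = FALSE)
  summaries$usable <- n_v >= min_replicates
  summaries$qc_pass <- summaries$usable &
    (summaries$template == "gDNA" | summaries$cv <= cv_threshold)
  summaries$mean_ratio[!summaries$usable] <- NA_real_
  summaries$sd_ratio[!summaries$usable] <- NA_real_
  summaries$cv[!summaries$usable] <- NA_real_
  summaries <- summaries[, c("sample_id", "assay_id", "template",
                             "mean_ratio", "sd_ratio", "cv", "n_replicates",
                             "qc_pass", "usable")]
  n_qc <- sum(summaries$usable & !summaries$qc_pass)
  if (n_qc) {
    log <- c(log, sprintf(
      "%d sample x assay cDNA summaries failed reproducibility QC (cv > %.2f)",
      n_qc, cv_threshold))
  }
  n_few <- sum(!summaries$usable)
  if (n_few) {
    log <- c(log, sprintf(
      "%d sample x assay x template summaries had < %d valid replicates",
      n_few, min_replicates))
  }
  list(summaries = summaries, corrections = corrections, log = log)
}
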