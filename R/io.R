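#' Read a sample/genotype table
#'
#' Parses a tab-separated sample table with columns `sample_id`, `tissue`,
#' then one column per locus holding unordered genotypes written `"X/Y"`
#' (`"."` or empty for missing). Genotypes are unordered: `"A/T"` and
#' `"T/A"` are the same genotype; phase is never read from input, always
#' inferred statistically downstream.
#'
#' @param path Path to a tab-separated file.
#' @param loci Locus table as from [study_loci()]; genotype columns are
#'   validated against it. Columns for loci not in the table are an error.
#' @return A `data.frame` (one row per sample) with attributes
#'   `n_read` and `n_bad_genotype` recording parse accounting. Genotype
#'   columns hold normalised `"X/Y"` strings (alleles sorted) or `NA`.
#' @details Unknown allele strings at a known locus are a hard error naming
#'   the offending row, as are duplicated sample ids. Empty or `"."` cells
#'   become missing genotypes with the record retained.
#' @export
read_samples <- function(path, loci = study_loci()) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  need <- c("sample_id", "tissue")
  if (!all(need %in% names(raw))) {
    stop("sample table must have columns 'sample_id' and 'tissue'", call. = FALSE)
  }
  gcols <- setdiff(names(raw), need)
  unknown <- setdiff(gcols, loci$locus_id)
  if (length(unknown)) {
    stop("sample table has genotype columns for unknown loci: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in sample table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (lc in gcols) {
    alleles <- unlist(locus_row(loci, lc)[, c("allele_ref", "allele_alt")])
    raw[[lc]] <- vapply(seq_along(raw[[lc]]), function(i) {
      parse_genotype(raw[[lc]][i], alleles, lc, row = i)
    }, character(1))
    raw[[lc]][raw[[lc]] == ""] <- NA_character_
  }
  attr(raw, "n_read") <- nrow(raw)
  attr(raw, "n_bad_genotype") <- 0L
  raw
}

# Normalise one genotype cell to "X/Y" with sorted alleles, "" for missing.
# Malformed pairs and alleles foreign to the locus are hard errors.
#' @keywords internal
parse_genotype <- function(cell, alleles, locus_id, row = NA) {
  cell <- trimws(cell)
  if (cell %in% c("", ".", "./.", "NA")) return("")
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(nzchar(parts))) {
    stop("malformed genotype '", cell, "' at locus ", locus_id,
         " (row ", row, ")", call. = FALSE)
  }
  if (!all(parts %in% alleles)) {
    stop("genotype '", cell, "' at locus ", locus_id, " (row ", row,
         ") uses alleles other than {", paste(alleles, collapse = ","), "}",
         call. = FALSE)
  }
  paste(sort(parts), collapse = "/")
}

#' Test heterozygosity / homozygosity of normalised genotype strings
#'
#' @param gt Character vector of `"X/Y"` genotypes (`NA` allowed).
#' @return Logical vector; `NA` where the genotype is missing.
#' @export
is_het <- function(gt) {
  out <- rep(NA, length(gt))
  ok <- !is.na(gt)
  parts <- strsplit(gt[ok], "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) p[1] != p[2], logical(1))
  out
}

#' Count copies of a given allele in genotype strings
#' @param gt Character vector of `"X/Y"` genotypes.
#' @param allele Single allele token.
#' @return Integer vector of 0, 1 or 2 (`NA` for missing genotypes).
#' @export
allele_dose <- function(gt, allele) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  parts <- strsplit(gt[ok], "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) sum(p == allele), integer(1))
  out
}

#' Read a peak-height table
#'
#' Parses the tab-separated measurement table with columns `plate_id`,
#' `sample_id`, `assay_id`, `template` (`gDNA` or `cDNA`), `replicate`
#' (1..4), `peak_a1`, `peak_a2`. `peak_a1` is the fluorescence peak height
#' of the expressed allele generally in phase with the risk alleles (fixed
#' per assay), `peak_a2` that of the alternative allele.
#'
#' @param path Path to a tab-separated file.
#' @param max_replicates Upper bound on the replicate index (default 4,
#'   the assay design).
#' @return `data.frame` of measurements; attribute `n_read` carries the row
#'   count.
#' @details Negative peak heights, replicate indices outside 1..4 and
#'   duplicated replicate indices within a sample/template/assay are hard
#'   errors. Zero peaks are loaded; the ratio step rejects them replicate-wise.
#' @export
read_peaks <- function(path, max_replicates = 4L) {
  if (!file.exists(path)) stop("peaks table not found: ", path, call. = FALSE)
  pk <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("plate_id", "sample_id", "assay_id", "template", "replicate",
            "peak_a1", "peak_a2")
  miss <- setdiff(need, names(pk))
  if (length(miss)) {
    stop("peaks table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pk$replicate <- as.integer(pk$replicate)
  pk$peak_a1 <- as.numeric(pk$peak_a1)
  pk$peak_a2 <- as.numeric(pk$peak_a2)
  if (!all(pk$template %in% c("gDNA", "cDNA"))) {
    stop("template must be 'gDNA' or 'cDNA'", call. = FALSE)
  }
  bad <- which(!is.finite(pk$peak_a1) | !is.finite(pk$peak_a2) |
                 pk$peak_a1 < 0 | pk$peak_a2 < 0)
  if (length(bad)) {
    stop("negative or non-finite peak height at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(pk$replicate) | pk$replicate < 1L |
                 pk$replicate > max_replicates)
  if (length(bad)) {
    stop("replicate index outside 1..", max_replicates, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(pk$sample_id, pk$template, pk$assay_id, pk$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated replicate index within sample/template/assay",
         call. = FALSE)
  }
  attr(pk, "n_read") <- nrow(pk)
  pk
}

#' Write sample / peak / result tables
#'
#' Writers mirror the reader schemas exactly so that write-then-read
#' round-trips reproduce identical records. Missing genotypes are written
#' as `"."`.
#'
#' @param x The table to write.
#' @param path Output path (tab-separated, UTF-8).
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path) {
  y <- x
  for (j in setdiff(names(y), c("sample_id", "tissue"))) {
    y[[j]][is.na(y[[j]])] <- "."
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
write_peaks <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
write_results <- function(x, path) {
  cols <- c("gene", "assay_id", "tissue", "risk_locus", "contrast",
            "mean_group1", "mean_group2", "n1", "n2", "levene_p",
            "welch_used", "t_stat", "df", "p_raw", "m_tests", "p_corrected",
            "percent_effect", "testable")
  x <- x[, intersect(cols, names(x)), drop = FALSE]
  fmt <- x
  for (j in c("mean_group1", "mean_group2", "percent_effect")) {
    if (j %in% names(fmt)) fmt[[j]] <- ifelse(is.na(x[[j]]), NA, sprintf("%.4f", x[[j]]))
  }
  for (j in c("levene_p", "t_stat", "df", "p_raw", "p_corrected")) {
    if (j %in% names(fmt)) fmt[[j]] <- ifelse(is.na(x[[j]]), NA, signif(x[[j]], 3))
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes at requested loci from a VCF file
#'
#' Maps biallelic GT fields to unordered allele pairs. For an indel locus
#' (alleles coded `"I"`/`"D"`), the longer of REF/ALT maps to `"I"` and the
#' shorter to `"D"`. Requires the `vcfR` package.
#'
#' @param path VCF file (v4.x), plain text or bgzipped.
#' @param loci Locus table restricted to the loci to extract; VCF IDs must
#'   match `locus_id`.
#' @param tissue Tissue label to assign to all samples (VCFs carry none).
#' @return Sample table in the [read_samples()] schema.
#' @export
read_vcf_genotypes <- function(path, loci, tissue = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_genotypes() requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF: vector, not matrix
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- which(fix$ID %in% loci$locus_id)
  if (!length(keep)) stop("no requested loci found in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  out <- data.frame(sample_id = samples, tissue = tissue,
                    stringsAsFactors = FALSE)
  for (i in keep) {
    id <- fix$ID[i]
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multiallelic record at requested locus ", id, call. = FALSE)
    }
    lr <- locus_row(loci, id)
    if (all(c(lr$allele_ref, lr$allele_alt) %in% c("I", "D"))) {
      # indel: longer sequence is the insertion allele
      code <- if (nchar(ref) >= nchar(alt)) c("I", "D") else c("D", "I")
    } else {
      code <- c(ref, alt)
      if (!setequal(code, c(lr$allele_ref, lr$allele_alt))) {
        stop("VCF alleles ", ref, "/", alt, " at ", id,
             " do not match locus definition", call. = FALSE)
      }
    }
    g <- gt[i, samples]
    g <- gsub("|", "/", g, fixed = TRUE)
    out[[id]] <- vapply(g, function(x) {
      if (is.na(x) || x %in% c("./.", ".")) return(NA_character_)
      idx <- as.integer(strsplit(x, "/", fixed = TRUE)[[1]]) + 1L
      if (length(idx) != 2L || anyNA(idx) || any(idx > 2L)) {
        return(NA_character_)
      }
      paste(sort(code[idx]), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
  }
  out
}
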