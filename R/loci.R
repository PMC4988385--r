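#' Define a biallelic locus
#'
#' A locus is a SNP or a biallelic indel. Indel alleles are coded `"I"`
#' (insertion) and `"D"` (deletion) in all tabular inputs. Risk variants
#' additionally declare which allele is the risk allele; expressed (exonic)
#' tag SNPs do not.
#'
#' @param locus_id Character identifier (e.g. an rs number).
#' @param allele_ref,allele_alt The two alleles, single tokens such as
#'   `"T"`, `"A"`, `"I"`, `"D"`. Must differ.
#' @param risk_allele Optional; one of the two alleles. Present only for
#'   risk variants.
#' @return A one-row `data.frame` with class `"ase_locus"` columns
#'   `locus_id`, `allele_ref`, `allele_alt`, `risk_allele` (`NA` when absent).
#' @examples
#' locus("rs11191419", "A", "T", risk_allele = "T")
#' locus("rs3740387", "C", "T")
#' @export
locus <- function(locus_id, allele_ref, allele_alt, risk_allele = NA_character_) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  allele_ref <- as.character(allele_ref)
  allele_alt <- as.character(allele_alt)
  if (identical(allele_ref, allele_alt)) {
    stop("locus '", locus_id, "': alleles must differ (got '",
         allele_ref, "' twice)", call. = FALSE)
  }
  if (!is.na(risk_allele) && !risk_allele %in% c(allele_ref, allele_alt)) {
    stop("locus '", locus_id, "': risk allele '", risk_allele,
         "' is neither '", allele_ref, "' nor '", allele_alt, "'",
         call. = FALSE)
  }
  out <- data.frame(locus_id = locus_id, allele_ref = allele_ref,
                    allele_alt = allele_alt, risk_allele = risk_allele,
                    stringsAsFactors = FALSE)
  class(out) <- c("ase_locus", class(out))
  out
}

#' Locus table for the chromosome 10q24 study design
#'
#' The two schizophrenia risk variants at chromosome 10q24 (SNP rs11191419,
#' risk allele T; indel ch10_104957618_I / rs202213518, risk allele D, the
#' deletion) together with the four exonic tag SNPs used to assay the
#' allelic expression of BORCS7 (rs4917985), AS3MT (rs1046778), CNNM2
#' (rs2275271) and NT5C2 (rs3740387).
#'
#' @return A `data.frame` with one row per locus (columns as in [locus()]).
#' @seealso [default_assays()] for the gene-to-tag-SNP map.
#' @export
study_loci <- function() {
  rbind(
    locus("rs11191419",       "A", "T", risk_allele = "T"),
    locus("ch10_104957618_I", "I", "D", risk_allele = "D"),
    locus("rs4917985",  "C", "T"),
    locus("rs1046778",  "T", "C"),
    locus("rs2275271",  "A", "G"),
    locus("rs3740387",  "C", "T")
  )
}

#' Assay definitions: gene, expressed tag SNP and numerator allele
#'
#' Each assay measures one gene through one exonic heterozygous SNP. The
#' numerator allele `allele_a1` is the expressed allele generally carried in
#' phase with the risk alleles; peak column `peak_a1` in the peaks table
#' refers to it. This orientation is fixed per assay by design, never
#' guessed from data.
#'
#' @return `data.frame` with columns `gene`, `assay_id` (the expressed SNP),
#'   `allele_a1`, `allele_a2`.
#' @export
default_assays <- function() {
  data.frame(
    gene      = c("BORCS7", "AS3MT", "CNNM2", "NT5C2"),
    assay_id  = c("rs4917985", "rs1046778", "rs2275271", "rs3740387"),
    allele_a1 = c("C", "T", "A", "C"),
    allele_a2 = c("T", "C", "G", "T"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
locus_row <- function(loci, locus_id) {
  i <- match(locus_id, loci$locus_id)
  if (is.na(i)) stop("unknown locus '", locus_id, "'", call. = FALSE)
  loci[i, , drop = FALSE]
}

#' Tissues recognised by the default study design
#' @return Character vector of tissue labels.
#' @export
default_tissues <- function() {
  c("DLPFC", "hippocampus", "caudate", "fetal_whole_brain")
}
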