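#' Tabulate two-locus genotype counts
#'
#' Builds the 3x3 table of joint genotype counts used for haplotype
#' frequency estimation. Rows index the genotype at locus 1 by copies of
#' its first allele (2, 1, 0: a1a1, a1a2, a2a2), columns likewise for
#' locus 2. Samples missing a genotype at either locus are dropped.
#'
#' @param samples Sample table as from [read_samples()].
#' @param locus1,locus2 Locus ids (columns of `samples`).
#' @param loci Locus table giving the allele coding.
#' @return 3x3 integer matrix with dimnames `c("a1a1","a1a2","a2a2")` x
#'   `c("b1b1","b1b2","b2b2")`, where allele a1 is `allele_ref` of locus 1
#'   and b1 is `allele_ref` of locus 2.
#' @export
two_locus_counts <- function(samples, locus1, locus2, loci = study_loci()) {
  l1 <- locus_row(loci, locus1); l2 <- locus_row(loci, locus2)
  d1 <- allele_dose(samples[[locus1]], l1$allele_ref)
  d2 <- allele_dose(samples[[locus2]], l2$allele_ref)
  ok <- !is.na(d1) & !is.na(d2)
  counts <- matrix(0L, 3, 3,
                   dimnames = list(c("a1a1", "a1a2", "a2a2"),
                                   c("b1b1", "b1b2", "b2b2")))
  for (i in which(ok)) counts[3L - d1[i], 3L - d2[i]] <-
    counts[3L - d1[i], 3L - d2[i]] + 1L
  counts
}

# Genotype-class probabilities for a 3x3 table under random mating,
# given haplotype frequencies f = (f11, f12, f21, f22).
#' @keywords internal
two_locus_genotype_probs <- function(f) {
  f11 <- f[1]; f12 <- f[2]; f21 <- f[3]; f22 <- f[4]
  matrix(c(
    f11^2,             2 * f11 * f12,                 f12^2,
    2 * f11 * f21,     2 * f11 * f22 + 2 * f12 * f21, 2 * f12 * f22,
    f21^2,             2 * f21 * f22,                 f22^2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("a1a1", "a1a2", "a2a2"), c("b1b1", "b1b2", "b2b2")))
}

#' @keywords internal
two_locus_loglik <- function(f, counts) {
  p <- two_locus_genotype_probs(f)
  sel <- counts > 0
  sum(counts[sel] * log(pmax(p[sel], .Machine$double.xmin)))
}

#' Two-locus haplotype frequencies by expectation-maximization
#'
#' Maximum-likelihood estimation of the four two-locus haplotype
#' frequencies (a1b1, a1b2, a2b1, a2b2) from unphased genotype counts
#' under random mating. Only the double-heterozygote cell is phase
#' ambiguous; the E-step splits it between the two consistent diplotypes
#' in proportion to their current expected frequencies, and the M-step is
#' gamete counting. The run is deterministic: EM is started from the
#' linkage-equilibrium product of the observed allele frequencies and,
#' because that point is a stationary saddle for strongly
#' double-heterozygote-weighted tables, additionally from two
#' disequilibrium-shifted starts (D at half its positive and negative
#' bounds); the highest-likelihood solution is returned, first start
#' winning ties.
#'
#' @param counts 3x3 genotype count matrix as from [two_locus_counts()].
#' @param tol Convergence tolerance: maximum absolute change in any
#'   haplotype frequency between iterations (default 1e-8).
#' @param max_iter Iteration cap (default 1000); non-convergence returns
#'   the current estimate with `converged = FALSE` and a warning.
#' @param trace If `TRUE`, record the observed-data log-likelihood at every
#'   iteration (element `loglik_trace`; it is non-decreasing).
#' @return A list of class `"ase_hapfreq"`: `f` (named numeric, sums to 1),
#'   `loglik`, `n_iter`, `converged`, `D`, `D_prime`, `r2`, and the margins
#'   `p_a1`, `q_b1`.
#' @examples
#' cts <- matrix(c(30, 0, 0, 0, 40, 0, 0, 0, 30), 3, 3, byrow = TRUE)
#' em_haplotype_frequencies(cts)$f  # complete coupling: (0.5, 0, 0, 0.5)
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-8, max_iter = 1000L,
                                     trace = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("need at least one sample typed at both loci", call. = FALSE)
  # allele-1 dose margins: rows a1a1,a1a2,a2a2 carry 2,1,0 copies of a1
  p_a1 <- sum(c(2, 1, 0) * rowSums(counts)) / (2 * n)
  q_b1 <- sum(c(2, 1, 0) * colSums(counts)) / (2 * n)
  if (p_a1 %in% c(0, 1) || q_b1 %in% c(0, 1)) {
    stop("monomorphic locus: haplotype frequencies not estimable", call. = FALSE)
  }
  n_dh <- counts["a1a2", "b1b2"]
  # unambiguous haplotype counts contributed by the eight other cells
  base <- c(
    a1b1 = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    a1b2 = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    a2b1 = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    a2b2 = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  )
  em_run <- function(f0) {
    f <- f0
    converged <- FALSE
    it <- 0L
    ll_trace <- if (trace) numeric(0) else NULL
    repeat {
      it <- it + 1L
      # E-step: split double heterozygotes between the two diplotypes
      w_cis <- f["a1b1"] * f["a2b2"]
      w_trans <- f["a1b2"] * f["a2b1"]
      h <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
      e <- base + n_dh * c(h, 1 - h, 1 - h, h)
      f_new <- e / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (trace) ll_trace <- c(ll_trace, two_locus_loglik(f, counts))
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    list(f = f, n_iter = it, converged = converged,
         loglik = two_locus_loglik(f, counts), ll_trace = ll_trace,
         delta = delta)
  }
  # starts: D = 0 (linkage equilibrium) and half the positive/negative
  # bounds on D given the margins
  start_f <- function(D) {
    c(a1b1 = p_a1 * q_b1 + D, a1b2 = p_a1 * (1 - q_b1) - D,
      a2b1 = (1 - p_a1) * q_b1 - D, a2b2 = (1 - p_a1) * (1 - q_b1) + D)
  }
  d_hi <- min(p_a1 * (1 - q_b1), (1 - p_a1) * q_b1)
  d_lo <- -min(p_a1 * q_b1, (1 - p_a1) * (1 - q_b1))
  runs <- lapply(c(0, d_hi / 2, d_lo / 2), function(D) em_run(start_f(D)))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  if (!best$converged) {
    warning("EM did not converge in ", max_iter, " iterations (last step ",
            format(best$delta), ")")
  }
  f <- best$f
  ld <- ld_from_f(f)
  structure(list(f = f, loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, D = ld["D"],
                 D_prime = ld["D_prime"], r2 = ld["r2"],
                 p_a1 = p_a1, q_b1 = q_b1, loglik_trace = best$ll_trace),
            class = "ase_hapfreq")
}

#' @export
print.ase_hapfreq <- function(x, ...) {
  cat("Two-locus haplotype frequencies (EM", if (x$converged) "converged"
      else "NOT converged", "in", x$n_iter, "iterations)\n")
  print(round(x$f, 4))
  cat(sprintf("D = %.4f  D' = %.3f  r2 = %.3f  logLik = %.3f\n",
              x$D, x$D_prime, x$r2, x$loglik))
  invisible(x)
}

#' @keywords internal
ld_from_f <- function(f) {
  p <- f[1] + f[2]           # freq allele a1
  q <- f[1] + f[3]           # freq allele b1
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    return(c(D = NA_real_, D_prime = NA_real_, r2 = NA_real_))
  }
  D <- f[1] - p * q
  Dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  D_prime <- if (Dmax > 0) abs(D) / Dmax else 0
  r2 <- D^2 / (p * (1 - p) * q * (1 - q))
  c(D = unname(D), D_prime = unname(D_prime), r2 = unname(r2))
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Standard pairwise LD coefficients: `D = f(a1b1) - p(a1) q(b1)`,
#' Lewontin's `D'` (|D| divided by its sign-appropriate maximum), and
#' `r2 = D^2 / (p(a1) p(a2) q(b1) q(b2))`.
#'
#' @param f Either an `"ase_hapfreq"` fit or a numeric vector of four
#'   haplotype frequencies ordered (a1b1, a1b2, a2b1, a2b2).
#' @return Named numeric vector `c(D, D_prime, r2)`; all `NA` if either
#'   locus is monomorphic.
#' @examples
#' ld_statistics(c(0.4, 0.2, 0.1, 0.3)) # D = 0.10, r2 ~ 0.167
#' @export
ld_statistics <- function(f) {
  if (inherits(f, "ase_hapfreq")) f <- f$f
  stopifnot(length(f) == 4, all(f >= 0), abs(sum(f) - 1) < 1e-6)
  ld_from_f(f)
}

#' Diplotype-1 probability for a double heterozygote
#'
#' A sample heterozygous at both a risk variant and an expressed SNP is
#' consistent with exactly two diplotypes. Under random mating, diplotype 1
#' (haplotypes A and B) has population frequency `2 fA fB` and diplotype 2
#' (haplotypes C and D) `2 fC fD`; the probability that the sample carries
#' diplotype 1 is the ratio of the first to their sum.
#'
#' @param fA,fB Frequencies of the two haplotypes composing diplotype 1.
#' @param fC,fD Frequencies of the two haplotypes composing diplotype 2.
#' @return `2 fA fB / (2 fA fB + 2 fC fD)`, in `[0, 1]`.
#' @examples
#' diplotype_probability(0.6, 0.3, 0.05, 0.05) # ~0.9863
#' @export
diplotype_probability <- function(fA, fB, fC, fD) {
  stopifnot(all(c(fA, fB, fC, fD) >= 0))
  d1 <- 2 * fA * fB
  d2 <- 2 * fC * fD
  if (d1 + d2 <= 0) {
    stop("both diplotypes have zero frequency: double heterozygote ",
         "impossible under these haplotype frequencies", call. = FALSE)
  }
  d1 / (d1 + d2)
}

#' Orient risk alleles against expressed alleles for double heterozygotes
#'
#' For every sample heterozygous at both the risk locus and the expressed
#' SNP, evaluates the probability that it carries diplotype 1, defined as
#' {risk allele with expressed allele a1} / {non-risk allele with expressed
#' allele a2}, from the EM haplotype frequencies. The call's orientation is
#' the more probable configuration; it is confident when
#' `max(p, 1 - p) >= threshold`. Samples homozygous or missing at either
#' locus receive no call.
#'
#' @param samples Sample table.
#' @param risk_locus,assay Risk locus id and one-row assay definition (a
#'   row of [default_assays()]).
#' @param fit `"ase_hapfreq"` fit for (risk locus, expressed SNP), with
#'   haplotype a1 = risk allele and b1 = the assay's `allele_a1`
#'   (use [phase_assay()] to construct it with this orientation).
#' @param threshold Confidence cutoff on the phase probability
#'   (default 0.90).
#' @param loci Locus table.
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `p_diplotype1`, `orientation` (`"risk_with_a1"` / `"risk_with_a2"` /
#'   `NA`), `confident`.
#' @export
orient_samples <- function(samples, risk_locus, assay, fit, threshold = 0.90,
                           loci = study_loci()) {
  rl <- locus_row(loci, risk_locus)
  risk <- rl$risk_allele
  if (is.na(risk)) stop("locus ", risk_locus, " has no risk allele", call. = FALSE)
  het_r <- is_het(samples[[risk_locus]])
  het_e <- is_het(samples[[assay$assay_id]])
  f <- fit$f
  # diplotype 1: haplotypes risk-a1 and nonrisk-a2
  p1 <- diplotype_probability(f["a1b1"], f["a2b2"], f["a1b2"], f["a2b1"])
  out <- data.frame(sample_id = samples$sample_id,
                    p_diplotype1 = NA_real_,
                    orientation = NA_character_,
                    confident = FALSE, stringsAsFactors = FALSE)
  callable <- !is.na(het_r) & !is.na(het_e) & het_r & het_e
  out$p_diplotype1[callable] <- p1
  out$orientation[callable] <- if (p1 >= 0.5) "risk_with_a1" else "risk_with_a2"
  out$confident[callable] <- max(p1, 1 - p1) >= threshold
  out
}

#' Estimate phase between a risk locus and an assay's expressed SNP
#'
#' Convenience wrapper: tabulates two-locus genotype counts with haplotype
#' allele 1 = the risk allele and allele b1 = the assay numerator allele,
#' runs the EM, and returns the fit (so that `f["a1b1"]` is the frequency
#' of the risk-allele / a1 haplotype).
#'
#' @inheritParams orient_samples
#' @param samples Sample table (typically the combined cohort, all tissues
#'   pooled).
#' @param tol,max_iter Passed to [em_haplotype_frequencies()].
#' @return An `"ase_hapfreq"` fit.
#' @export
phase_assay <- function(samples, risk_locus, assay, loci = study_loci(),
                        tol = 1e-8, max_iter = 1000L) {
  rl <- locus_row(loci, risk_locus)
  risk <- rl$risk_allele
  nonrisk <- setdiff(c(rl$allele_ref, rl$allele_alt), risk)
  oriented_loci <- rbind(
    locus(risk_locus, risk, nonrisk, risk_allele = risk),
    locus(assay$assay_id, assay$allele_a1, assay$allele_a2)
  )
  cts <- two_locus_counts(samples, risk_locus, assay$assay_id,
                          loci = oriented_loci)
  em_haplotype_frequencies(cts, tol = tol, max_iter = max_iter)
}

#' Hardy-Weinberg equilibrium chi-square test for one biallelic locus
#'
#' Asymptotic 1-df chi-square comparing observed genotype counts with the
#' expectations implied by the sample allele frequency; no continuity
#' correction.
#'
#' @param n_aa,n_ab,n_bb Counts of the three genotype classes.
#' @return Named numeric `c(chi2, p)`; both `NA` when the locus is
#'   monomorphic in the sample.
#' @examples
#' hwe_test(25, 50, 25) # exact HWE: chi2 = 0, p = 1
#' hwe_test(10, 10, 10) # chi2 = 10/3, p ~ 0.068
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  stopifnot(n >= 1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p <= 0 || p >= 1) return(c(chi2 = NA_real_, p = NA_real_))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg screen across all genotyped loci
#'
#' @param samples Sample table.
#' @param loci Locus table; loci absent from `samples` are skipped.
#' @return `data.frame` with `locus_id`, genotype counts, `chi2`, `p`.
#' @export
hwe_screen <- function(samples, loci = study_loci()) {
  present <- intersect(loci$locus_id, names(samples))
  do.call(rbind, lapply(present, function(lc) {
    d <- allele_dose(samples[[lc]], locus_row(loci, lc)$allele_ref)
    cts <- c(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 0, na.rm = TRUE))
    tst <- hwe_test(cts[1], cts[2], cts[3])
    data.frame(locus_id = lc, n_aa = cts[1], n_ab = cts[2], n_bb = cts[3],
               chi2 = unname(tst["chi2"]), p = unname(tst["p"]),
               stringsAsFactors = FALSE)
  }))
}
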