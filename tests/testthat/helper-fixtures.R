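# Shared fixture builders. Everything is generated in code at test time.

# A tiny hand-written cohort: 4 samples, one assay (NT5C2 / rs3740387),
# one risk locus (ch10_104957618_I), one plate.
tiny_samples <- function() {
  s <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    tissue = c("DLPFC", "DLPFC", "DLPFC", "hippocampus"),
    stringsAsFactors = FALSE)
  s[["ch10_104957618_I"]] <- c("D/I", "D/I", "D/D", "D/I")
  s[["rs3740387"]] <- c("C/T", "C/T", "C/T", NA)
  s
}

tiny_peaks <- function(ratio_cdna = 1.2, bias = 1.0, n_rep = 4) {
  rows <- list()
  for (sid in c("S1", "S2", "S3")) {
    for (tpl in c("gDNA", "cDNA")) {
      r <- if (tpl == "cDNA") ratio_cdna else 1
      rows[[paste(sid, tpl)]] <- data.frame(
        plate_id = "P1", sample_id = sid, assay_id = "rs3740387",
        template = tpl, replicate = seq_len(n_rep),
        peak_a1 = 1000 * bias * r, peak_a2 = 1000,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Independent grid-search oracle for the two-locus haplotype MLE.
# Re-derives the genotype-class probabilities from first principles
# (diplotype enumeration), so it shares no code with the EM.
grid_loglik_max <- function(counts, step = 0.01) {
  cnt <- as.vector(t(counts))  # row-major: a1a1 x (b1b1,b1b2,b2b2), ...
  fs <- seq(0, 1, by = step)
  best <- -Inf
  for (f1 in fs) for (f2 in fs) {
    if (f1 + f2 > 1 + 1e-12) break
    f34 <- 1 - f1 - f2
    for (f3 in fs[fs <= f34 + 1e-12]) {
      f4 <- max(0, f34 - f3)
      p <- c(f1^2, 2 * f1 * f2, f2^2,
             2 * f1 * f3, 2 * f1 * f4 + 2 * f2 * f3, 2 * f2 * f4,
             f3^2, 2 * f3 * f4, f4^2)
      sel <- cnt > 0
      if (any(p[sel] == 0)) next
      ll <- sum(cnt[sel] * log(p[sel]))
      if (ll > best) best <- ll
    }
  }
  best
}

# Vectorised version used when many tables are checked against one grid:
# precompute log genotype probabilities over the whole simplex grid once.
grid_logprob_matrix <- function(step = 0.01) {
  fs <- seq(0, 1, by = step)
  g <- expand.grid(f1 = fs, f2 = fs, f3 = fs)
  g <- g[g$f1 + g$f2 + g$f3 <= 1 + 1e-9, ]
  f4 <- pmax(0, 1 - g$f1 - g$f2 - g$f3)
  P <- cbind(g$f1^2, 2 * g$f1 * g$f2, g$f2^2,
             2 * g$f1 * g$f3, 2 * g$f1 * f4 + 2 * g$f2 * g$f3,
             2 * g$f2 * f4,
             g$f3^2, 2 * g$f3 * f4, f4^2)
  log(pmax(P, 1e-300))
}

grid_loglik_max_fast <- function(counts, logP) {
  cnt <- as.vector(t(counts))
  max(logP %*% cnt)
}

counts_matrix <- function(v) {
  matrix(as.integer(v), 3, 3, byrow = TRUE,
         dimnames = list(c("a1a1", "a1a2", "a2a2"),
                         c("b1b1", "b1b2", "b2b2")))
}

# All 3x3 nonnegative integer tables with given total (compositions).
all_tables_with_total <- function(n) {
  out <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 1) { out[[length(out) + 1L]] <<- c(prefix, remaining); return() }
    for (k in 0:remaining) rec(c(prefix, k), remaining - k, slots - 1)
  }
  rec(integer(0), n, 9)
  out
}
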