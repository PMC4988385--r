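---
title: "Measuring cis-regulatory effects from allele-specific expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cis-regulatory effects from allele-specific expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepipe)
```

This vignette is the package's account of its statistical machinery: the
measurement model behind corrected allelic ratios, the two-locus phasing
model, the contrast design, the generative simulator, and the numerical
and design choices made where more than one defensible option existed.

## 1. The measurement model

A primer-extension ASE assay reports two fluorescence peak heights per
reaction, one per allele of an exonic tag SNP. For a sample heterozygous
at that SNP, the ratio

$$ r = \frac{\text{peak}_{a1}}{\text{peak}_{a2}} $$

estimates the relative abundance of the two allelic templates. Allele
$a1$ is defined per assay as the expressed allele *generally in phase
with the risk allele*; this orientation is part of the assay definition
(`default_assays()`), never inferred from data, so the sign of every
downstream effect has a fixed meaning.

Two multiplicative nuisances sit between template abundance and peak
height:

* an **assay-specific allelic bias** $b$ (unequal incorporation or
  detection efficiency of the two extension products), identical for
  genomic DNA and cDNA because both templates run through the same
  chemistry; and
* **replicate noise**, well described as multiplicative and
  heavy-tailed-ish, which we model log-normally.

Genomic DNA from a heterozygote is a physical 1:1 standard: its expected
raw ratio is exactly $b$. The pipeline therefore averages the raw gDNA
ratios of heterozygous samples on each plate, per assay, and divides
every ratio on that plate by this **correction factor**. Two exact
consequences, both asserted in the test suite, follow by construction:

* the mean corrected gDNA ratio across the samples defining a plate's
  factor is exactly 1; and
* corrected ratios are invariant to any common rescaling of the $a1$
  peaks on a plate (the mechanism removes the bias it is designed to
  remove, exactly, in the noise-free limit).

Replicate summaries use the mean and the $n-1$ (sample) standard
deviation of 2–4 valid replicates. Replicates with a non-positive peak
are invalid and dropped rather than imputed; a summary needs at least two
valid replicates — the mechanical minimum for a mean and SD, chosen here
because the upstream protocol is silent. The reproducibility filter
excludes cDNA summaries with coefficient of variation $\mathrm{sd}/\mathrm{mean} > 0.25$;
it applies to cDNA only (gDNA enters the contrasts as the reference
group) and at the sample × assay level, so a sample failing QC for one
gene is retained for others. Because the plate correction is a common
positive scalar, the CV — and hence the QC decision — is identical on raw
and corrected ratios.

Effect sizes are reported as $(\bar r - 1) \times 100$ percent: a mean
corrected cDNA ratio of 0.85 is a 15% reduction of the risk-phase
allele's expression.

## 2. Two-locus phasing

Genotypes are read as unordered allele pairs; phase between the risk
variant and each tag SNP is always inferred statistically. With four
haplotypes $(a_1b_1, a_1b_2, a_2b_1, a_2b_2)$ at frequencies $f$, and
random mating, every cell of the 3×3 joint genotype table has a known
probability; only the double heterozygote is phase-ambiguous. The EM
algorithm (`em_haplotype_frequencies()`):

* E-step — split the double-heterozygote count between the two consistent
  diplotypes in proportion to $f_{11}f_{22}$ and $f_{12}f_{21}$;
* M-step — gamete counting;
* convergence — maximum absolute frequency change below `tol = 1e-8`,
  cap `max_iter = 1000`.

**Initialisation.** The natural linkage-equilibrium start (product of
observed allele frequencies) is an *exact stationary point* of EM
whenever the data are dominated by double heterozygotes — for the
all-double-heterozygote table it is a saddle where EM cannot move, while
the maximum-likelihood solutions lie on the boundary of the simplex. The
package therefore runs EM from three deterministic starts — linkage
equilibrium, and $D$ at half its positive and negative bounds given the
margins — and keeps the highest-likelihood solution, the first start
winning ties. The procedure remains fully deterministic, and the test
suite verifies against an exhaustive 0.01-step grid search of the
multinomial likelihood (hundreds of small tables, exhaustively enumerated
up to total count 4 and randomly sampled up to 20) that the EM solution's
likelihood is never more than $10^{-6}$ below the grid maximum. EM also
preserves the sample allele-frequency margins at every iteration and has
a non-decreasing observed-data log-likelihood, both asserted directly.

Haplotype frequencies are estimated on the pooled cohort (all tissues),
the configuration with the most genotyped samples; LD is summarised by
$D$, Lewontin's $D'$ and $r^2$.

**Diplotype probability and orientation.** For a sample heterozygous at
both loci, diplotype 1 (risk allele with $a1$) has frequency
$2f_Af_B$ and diplotype 2 (risk with $a2$) $2f_Cf_D$; the probability of
diplotype 1 is their ratio. This probability depends only on $f$, so it
is shared by all double heterozygotes for a locus pair. Samples are
confidently oriented when $\max(p, 1-p)$ reaches the configured
threshold, default **0.90**: designs of this kind rest on strong regional
LD with reported phase certainties of 0.94–0.99+, and 0.90 excludes
locus pairs whose phase is genuinely uncertain while tolerating
moderate estimation noise in $f$. Below threshold, all double
heterozygotes for the pair are excluded, with a logged count.

**Hardy-Weinberg screening** uses the asymptotic 1-df chi-square without
continuity correction — the simplest standard screen; an exact test is a
reasonable alternative at very small minor-allele counts but is not
needed at the cohort sizes this design targets.

## 3. Contrasts and multiplicity

Two families of comparisons, both on per-sample mean corrected ratios:

* **cDNA vs gDNA in risk-allele heterozygotes** — detects any average
  departure of the risk-phase allele's expression from the 1:1 genomic
  standard. Implemented as an *unpaired* two-sample t-test between the
  cDNA means of confidently oriented double heterozygotes and the same
  samples' gDNA means. The unpaired form was chosen because the
  comparison is described, and plotted, as two groups of observed ratios;
  a paired test within samples is the natural alternative and would
  typically be more powerful, but changes the estimand (mean within-pair
  difference) relative to the group-mean contrast reported here. The
  gDNA group is restricted to the same samples as the cDNA group — the
  tighter reading, which keeps the two groups exchangeable apart from
  template.
* **Heterozygotes vs homozygotes at the risk variant**, cDNA only — tests
  whether genotype at the variant can account for the imbalance:
  cis-effects differ between the chromosomes of a heterozygote but are
  equal in a homozygote, so homozygote cDNA ratios should sit near 1
  regardless of any cis-effect of that variant. Both homozygote classes
  are pooled (at a risk-allele frequency of 0.9 the non-risk homozygote
  is rare).

Each contrast is gated by **Levene's test** with mean centering — the
classic form and the SPSS default, hence the one matching the upstream
analysis convention; Brown-Forsythe median centering is available via an
argument. When Levene's $P < 0.05$ the t-test assumes unequal variances
(Welch-Satterthwaite); otherwise the pooled-variance form is used. All
tests are two-tailed. Degenerate inputs follow explicit contracts rather
than erroring mid-pipeline: identical zero-variance groups give
$t = 0, p = 1$ (and Levene $W = 0, p = 1$), and zero-variance groups with
different means give $p = 0$ — both arise in noise-free simulations.

**Bonferroni families are fixed design constants**: 32 for the
cDNA-vs-gDNA family (2 risk variants × 4 genes × 4 tissues) and 16 for
het-vs-hom (1 variant × 4 genes × 4 tissues), attached to the family and
*not* recomputed from the number of contrasts actually run, so that
subset analyses reproduce the same corrected values. Corrected P is
$\min(1, mP)$.

Contrasts with fewer than 2 usable samples in either group are flagged
`testable = FALSE` and emit no P-value; testable groups smaller than 5
trigger a log warning. Output ratios are serialised at 4 decimals and
P-values at 3 significant figures, making reruns byte-comparable.

## 4. The generative simulator

`simulate_cohort()` emulates the assay design end to end: each sample
draws two haplotypes i.i.d. from the configured frequencies (so genotypes
are in Hardy-Weinberg proportions at the diplotype level); gDNA peaks are
`baseline × bias(allele) × noise`; cDNA peaks additionally multiply the
expressed allele on each *risk-bearing chromosome* by the allelic fold
change $\rho$. Acting on chromosomes rather than genotypes means
incomplete LD naturally attenuates the observed group mean below $\rho$:
a double heterozygote carrying the minority diplotype has true ratio
$1/\rho$ but is oriented with the majority, exactly the "generally in
phase" caveat of the assay design. Risk homozygotes have true ratio 1.
Noise is independent log-normal per peak per replicate; the assay bias is
shared by both templates, making it removable by the plate correction —
the confound the design is built around, so the simulator must generate
it. Peaks are emitted only for samples heterozygous at the tag SNP (the
samples the assay measures); each sample's replicates and templates stay
on one plate.

Default configuration (chosen once, as the study conditions the package
emulates):

| parameter | default | rationale |
|---|---|---|
| `n_per_tissue` | 40/38/38 adult + 95 fetal | 116 adult + 95 fetal samples before informativeness filtering |
| `haplotype_freqs` | (0.55, 0.35, 0.002, 0.098) | risk-allele frequency 0.90; double-het phase probability ≈ 0.99, the reported certainty for the default locus pair |
| `fold_change` | 0.85 | a 15% allelic reduction, the scale of the headline adult-brain effect |
| `assay_bias` | 1.2 | a moderate, realistic primer-extension bias |
| `noise_sd` | 0.1 | log-scale SD giving replicate CVs well inside the 0.25 QC gate |
| `baseline_signal` | 2000 | typical fluorescence peak height |
| `n_replicates`, `n_plates` | 4, 3 | the 4-replicate plate design |

The RNG is seeded locally per `simulate_cohort()` call and the caller's
`.Random.seed` is restored, so simulation is bit-reproducible and free of
global state.

**What the simulator does not emulate:** PCR saturation and
amplification-cycle compression of peak heights, RNA degradation and
RIN-correlated variance, age/sex structure, genotyping error, >2-locus
haplotype structure, and between-gene correlation of expression. Passing
calibration tests therefore show that the *statistical chain* is correct
and calibrated under its stated assumptions — not that those assumptions
exhaust real brain-bank data.

## 5. Calibration experiments and problem sizes

`recovery_experiment()` repeats simulate → ratios → phase → contrast and
summarises the estimated fold change (mean corrected cDNA ratio of
confidently oriented double heterozygotes) and the rejection rate at
$\alpha = 0.05$. The packaged checks use: 2000 null cohorts sized to give
about 40 informative double heterozygotes each (single tissue, 365
samples) for the type-I error band $0.05 \pm 3\,\mathrm{SE}$; 500 cohorts
at $\rho = 1.15$ and $1.4$ (about 20 informative heterozygotes each,
matching the sparser informative subsets of a real cohort) for recovery
within 2%; and noise-free runs for the exact identities (corrected ratio
$= \rho$; gDNA bias residual $= 0$). With phase certainty ≈ 0.99 the
expected attenuation of the recovered mean is ≈ $0.99\rho + 0.01/\rho$,
about half a percent at $\rho = 1.4$ — visible in the recovery output and
well inside the 2% band; at lower phase certainty it grows and is a real
feature of the estimand, not an estimator defect.

## 6. Known limitations

* The per-plate correction follows the literal protocol; pooling gDNA
  across plates would trade plate-effect removal for a steadier factor on
  sparse plates and is not implemented.
* Orientation flips (locus pairs where the risk allele travels with $a2$)
  invert summary-level means ($1/\bar r$), not replicate-level ratios;
  for the CV-gated summaries involved the difference is negligible, but
  it is a choice.
* The het-vs-hom contrast pools both homozygote classes; with common risk
  alleles the non-risk homozygote group is too small to analyse
  separately, which is also why one risk variant in the motivating design
  could not be tested in this family at all.
* P-values come from t-distributions on group sizes that can be small;
  the type-I calibration covers the simulator's log-normal noise, not
  arbitrary error distributions.
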