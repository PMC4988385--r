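Package: asepipe
Title: Allele-Specific Expression Analysis with Plate-Corrected Allelic
    Ratios and Two-Locus Phase Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cis-regulatory effects of candidate risk
    variants from primer-extension allele-specific expression assays.
    Converts allele peak heights into genomic-DNA-corrected allelic
    expression ratios with replicate-level quality control, estimates
    two-locus haplotype frequencies from unphased genotypes by
    expectation-maximization to orient risk alleles against expressed
    alleles via diplotype probabilities, and performs variance-gated
    t-test contrasts (cDNA versus genomic DNA in risk-allele
    heterozygotes, and heterozygotes versus homozygotes) with fixed
    Bonferroni families. Includes a generative simulator of genotype and
    peak-height cohorts for power, calibration and parameter-recovery
    studies, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
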