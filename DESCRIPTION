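Package: eparscan
Title: Sperm Crossover Analysis and Recombination History of the Extended
    Human Pseudoautosomal Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sperm-typing recombination assays and population-scale
    recombination inference in the extended pseudoautosomal region (ePAR) of
    the human sex chromosomes. Classifies per-molecule SNP typing calls from
    full and half allele-specific PCR assays into crossover and non-crossover
    (gene conversion) classes, estimates recombination fractions with exact
    Poisson confidence intervals, fits Gaussian hotspot morphologies to
    breakpoint distributions, and tests for transmission distortion and
    GC-biased gene conversion. Computes haplotype-based linkage
    disequilibrium (|D'|) landscapes from phased X-chromosomal panels with
    X-specific Hardy-Weinberg filtering, partitions markers into haplotype
    blocks that exclude double-strand-break clusters, reconstructs
    single-crossover explanations of compound haplotypes, and estimates
    lineage ages from Y-STR profiles by the average-squared-distance (ASD)
    method. A synthetic data module generates sperm molecule sets, phased
    haplotype panels and Y-lineage genealogies with known truth records for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
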