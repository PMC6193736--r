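---
title: "Methods: sperm crossover assays and ePAR recombination history"
author: "eparscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sperm crossover assays and ePAR recombination history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eparscan)
```

## The measurement model

Sperm-typing assays amplify single molecules from pools of sperm DNA and
type the heterozygous SNPs between allele-specific primer (ASP) sites. Two
designs are supported, and they carry different information:

* **Full assays** place ASPs from *opposite* parental haplotypes at the two
  ends, so only recombinant molecules amplify. A molecule showing exactly
  one haplotype switch is a crossover (CO), localized to the inter-marker
  interval between the flanking discordant markers. Two or more switches
  are reported as `complex` and excluded from rates; a switch-free molecule
  contradicts the selection and is `unscorable`.
* **Half assays** amplify one haplotype with ASPs plus universal primers and
  detect recombinants by probing for opposite-haplotype alleles. They see
  both COs and non-crossovers (NCOs, gene conversions): an internal run of
  opposite alleles flanked by selected alleles is an NCO; a switch
  persisting to the universal-primer end is a CO. A switch confined to the
  single terminal marker next to the universal primer is genuinely
  class-ambiguous (`terminal_ambiguous`); `apportion_terminal_events()`
  assigns half of such events to each class by default, with `all_CO` /
  `all_NCO` policies available to bound the extremes. Counts may therefore
  be fractional.

Missing calls are carried, not imputed: a switch is placed in the smallest
interval consistent with the non-missing calls, and a molecule whose class
is itself ambiguous is `unscorable`. Classification never guesses.

## Rates and intervals

`estimate_rf()` reports `k/N` with the exact (Garwood) chi-square Poisson
interval for the count, divided by `N`. Exactness matters at the small
counts these assays produce (tens of events); a normal approximation is
available by flag but is not the default. Note that the Poisson interval is
conservative; at `k = 158` its lower bound (0.175%) sits half a rounding
unit below a printed two-decimal value of 0.18%, which is why downstream
comparisons should use the unrounded bounds.

Two donors are compared conditionally: given `k1 + k2` total events, `k1`
is Binomial with success probability `N1/(N1+N2)` under rate equality.
Two-tailed P-values here and in `transmission_test()` double the smaller
tail and cap at 1 — a deliberate, reproducible convention chosen over
minimum-likelihood summation, since the two differ for asymmetric nulls.

Credible intervals for transmission frequencies use the Beta(k+1, n−k+1)
posterior under a uniform prior, equal-tailed rather than HPD so that the
interval is an explicit quantile pair anyone can recompute.

## Hotspot morphology

Breakpoints are only known to an inter-marker interval, so
`fit_normal()` fits the Gaussian *cumulative* curve to the empirical
cumulative breakpoint proportion evaluated at marker positions, each event
counted at its interval's right marker. Fitting the CDF rather than a
histogram avoids inventing within-interval positions and makes the fit
independent of interval widths; the cost is that centre estimates from
cumulative and histogram fits can differ by a few bp, which matters only
when comparing centres at sub-10-bp resolution. The fit is a deterministic
grid search (101 centre values across the marker span, 41 log-spaced sigma
values) refined by Nelder-Mead with a relative tolerance of 1e-12 on the
RSS; degenerate inputs (all events in one interval) are rejected with an
error rather than returning an unidentifiable sigma. Standard errors come
from the numerical Jacobian of the fitted CDF at the optimum.

Reported derived quantities: the 95% hotspot width `3.92 * sigma`, and peak
activity `total cM x N(0; 0, sigma) x 1e6` in cM/Mb. A crossover whose
flanking markers are not adjacent (missing internal calls) contributes to
each spanned interval proportionally to physical length, so the per-interval
genetic lengths always sum to `100 k / N` cM exactly.

## LD landscape and its filters

`dprime_matrix()` computes haplotype-based |D′| from phased panels (males
one X haplotype, females two; sex always comes from an explicit table). An
EM gamete-frequency estimator (`em_gamete_frequencies()`) is provided for
unphased diploid genotypes but is not the default route. Markers pass a
minor-allele-frequency filter (default MAF > 0.2) and a 2-df X-chromosomal
Hardy-Weinberg statistic that sums a female-genotype HWE chi-square and a
male/female allele-frequency-equality chi-square; the exact-test variant of
that framework is out of scope.

"Regions of LD breakdown" are an operational reading of a heat map, so
`ld_breakdown_regions()` makes the criterion explicit: for each adjacent
marker gap, the mean |D′| over all cross pairs within a 4-marker window on
each side is computed, and gaps below a threshold (default 0.5) are merged
into maximal intervals. Window and threshold are analysis parameters with
no canonical published value; they are recorded in the output provenance so
overlap counts against DSB clusters are always interpretable.

## Haplotype blocks and the single-crossover model

Markers inside DSB clusters are excluded and the remaining runs form
blocks, indexed from the distal end (`define_blocks()`). Compound-haplotype
identity is exact string equality per block; the modal compound haplotype
is the consensus, with ties flagged rather than silently broken.

The single-crossover model is oriented by chromosome mechanics: at any
crossover the ePAR-carrying Y retains its proximal (Y-specific-adjacent)
side, so incoming X material lies distal of the breakpoint. The breakpoint
is reported as the block boundary immediately proximal of the most proximal
differing block — a between-block index, not a bp interval, because the
intervening markers were deliberately excluded. Blocks distal of the
breakpoint that happen to match the consensus are attributed to
coincidental identity and included in the incoming haplotype. Single-SNP
block differences could equally be mutations; the per-block SNP-difference
counts are reported so the user can judge, and the package never classifies
mutation versus recombination.

`min_recombination_events()` is the count of distinct compound haplotypes
minus one. It is a true lower bound: each crossover (or mutation) changes
one lineage's state and can create at most one new distinct haplotype.

## ASD dating and the minimum rate

Under the stepwise mutation model the expected average squared distance of
repeat counts from the founder grows as `mu * t` per locus, so each locus
dates the radiation at `t_l = ASD_l / mu_l` generations. The point estimate
averages `t_l` over loci (rather than pooling ASD over pooled mu, which
weights loci by mutation rate), and the uncertainty is a
leave-one-locus-out jackknife; both choices are recorded in the output
provenance since published ± values rarely state their method. The founder
defaults to the per-locus modal repeat count, with an explicit override for
network-rooted founders. Bilocal markers (DYS385a/b) are treated as
exchangeable columns matched to minimize squared distance to the founder
pair. Years use a default generation time of 31.

`min_rate(events, generations, lineages)` implements the star-genealogy
formula exactly and is labelled a lower bound twice over: the event count
is a parsimony minimum, and a star genealogy maximizes the meioses
available. Real genealogies bifurcate, so the true rate can only be higher.

## What the synthetic data emulate — and what they do not

The generators' default parameters are the study-scale conditions used
throughout the tests:

* `simulate_sperm_molecules()`: recombinant count Binomial(`n_sperm`,
  `rf`); CO breakpoints and NCO tract centres Gaussian around the hotspot
  centre (truncated to the marker span); NCO tract lengths geometric with a
  default mean of 300 bp, reflecting that observed conversions are short,
  single-site events with maximal tract bounds of 1.9–2.8 kb set only by
  marker spacing; orientation drawn with probability `f_bias`, the
  transmission-distortion dial. Recombinants whose flipped-marker set is
  empty are undetectable by the assay and appear only in the truth record —
  exactly the censoring a real assay has.
* `simulate_x_panel()`: two ancestral haplotypes per segment with lineage
  switches allowed only at hotspot positions; a switching haplotype takes
  the *opposite* lineage, so cross-hotspot |D′| decays as `|1 − 2m|` for
  mixing proportion `m` while within-segment |D′| stays 1. Segment lineage
  frequencies are kept in [0.25, 0.75] so the MAF > 0.2 filter retains
  markers. This targets LD morphology only: there is no mutation, no
  gene-tree depth, no demographic realism, so passing LD tests shows the
  caller localizes hotspot-shaped LD decay, not that it handles real-panel
  noise such as low-MAF markers, genotyping error, or gradual decay.
* `simulate_epar_genealogy()`: star topology by default (each lineage
  evolves `t` generations independently from the founder), matching the
  minimum-rate formula, with a bifurcating option for the lower-bound
  property tests; STRs follow a vectorized symmetric stepwise model;
  crossovers replace all blocks distal of a uniform between-block
  breakpoint with blocks from a panel haplotype.

One seed governs each generator call; substreams are consumed in a fixed
documented order, so identical (parameters, seed) give byte-identical
output.

## Numerical choices and test scales

Tolerances and sizes used by the test-suite calibrations, chosen as the
smallest scales at which the binomial noise floor sits comfortably below
the tolerance being checked: interval-coverage checks use 2,000 replicates
(binomial SE ≈ 0.5% at 95%), Gaussian-recovery checks 100 assays of ~150
events, lower-bound and ASD-linearity checks 200 genealogies per condition,
and LD-hotspot localization 50 seeds. Exact-test enumeration is exhaustive
for all n ≤ 30.

## Known limitations

* Complex molecules (≥2 switches) are counted but not modelled; PCR
  artefacts (jumping PCR, allele dropout) beyond the `unscorable` class are
  out of scope.
* The per-pool deduplication of identical recombinants is left to the input
  table; every typed molecule is counted.
* The published gametic ratio convention is sensitive to rounding of RF and
  f; `gametic_ratio()` documents the formula and should be fed unrounded
  inputs.
* The LD-breakdown caller's window/threshold defaults are reasonable, not
  canonical; published correspondence counts depending on a visual call are
  not regression targets.
* `asd_tmrca()` requires strictly positive mutation rates (the estimator
  `ASD/mu` is undefined at `mu = 0`); a mutation-free scenario is simulated
  with a vanishingly small rate instead.
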