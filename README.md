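# eparscan

Sperm-based crossover analysis and population recombination history for the
extended human pseudoautosomal region (ePAR).

Pseudoautosomal region 1 (PAR1) at the tips of the human sex-chromosome short
arms supports the obligate crossover of male meiosis. In a subset of men an
X-to-Y translocation of ~110 kb has extended PAR1 proximally (the "ePAR"),
and the question is whether this extension is itself recombinationally
active. `eparscan` implements the analysis chain used to answer that
question from two directions:

* **de novo gametes** — classify per-sperm-molecule SNP typing calls from
  allele-specific PCR assays into crossover (CO), non-crossover
  (gene-conversion, NCO) and ambiguous classes, estimate recombination
  fractions with exact Poisson confidence intervals, fit the Gaussian
  morphology of the hotspot, and test for transmission distortion and
  GC-biased gene conversion; and
* **population history** — compute the |D'| linkage-disequilibrium landscape
  of phased X-chromosomal panels under X-specific Hardy-Weinberg filtering,
  partition markers into haplotype blocks that exclude meiotic
  double-strand-break (DSB) clusters, explain extant Y-borne ePAR haplotypes
  as single crossovers with incoming X material, and convert Y-STR-based
  TMRCA estimates into a minimum per-meiosis recombination rate.

A synthetic-data module generates sperm molecule sets, phased panels and
Y-lineage genealogies with known truth, so that every stage can be exercised
and calibrated without external downloads.

## The statistics at the core

* **Recombination fraction.** For `k` recombinant molecules among `N` sperm
  screened, `RF = k/N`; the 95% CI is the exact (Garwood) chi-square Poisson
  interval for `k` divided by `N`: `[qchisq(0.025, 2k)/2, qchisq(0.975, 2k+2)/2] / N`.
  1% RF over a region equals 1 cM of genetic length.
* **Hotspot morphology.** Crossovers are only localized to inter-marker
  intervals, so the Gaussian CDF `F(x; mu, sigma)` is least-squares fitted to
  the cumulative breakpoint proportion at marker positions. The hotspot
  width is the central 95% interval, `3.92 * sigma`; peak activity is the
  total genetic length times the fitted density at `mu`, in cM/Mb.
* **Transmission distortion.** Exact binomial tests of `k` of `n`
  recombinants carrying a focal allele against 0.5, with equal-tailed 95%
  credible intervals from the Beta(k+1, n-k+1) posterior, and the gametic
  ratio `(50 + d):(50 - d)` with `d = 100 * RF * (f - 0.5)`.
* **LD landscape.** Haplotype-based `D' = D / Dmax` with
  `D = p_AB - p_A p_B`, after filtering markers at MAF > 0.2 and a 2-df
  X-chromosomal Hardy-Weinberg test (female HWE plus male/female
  allele-frequency equality).
* **Minimum historical rate.** With `H` distinct compound haplotypes among
  `L` lineages radiating `G` generations from a common ancestor (ASD dating:
  `t = mean over loci of ASD_l / mu_l`), at least `H - 1` crossovers
  happened, giving `rate >= (H - 1)/(G * L)` per meiosis, converted to cM/Mb
  by `100 * rate / (length/1e6)`.

## Worked example

```r
library(eparscan)

# distal full-assay counts for the two sperm donors
e53 <- estimate_rf(158, 76800)
e20 <- estimate_rf(42, 92000)
print(e53)
#> RF = 0.21% (95% CI 0.17-0.24%), 158 recombinants / 76800 sperm [garwood]
print(e20)
#> RF = 0.05% (95% CI 0.03-0.06%), 42 recombinants / 92000 sperm [garwood]
cmp <- compare_rates(e53, e20)
#> fold difference: 4.5, P = 6e-22

# GC bias among non-crossovers: 9 of 10 conversions acquired the strong allele
transmission_test(9, 10, tail = "one", marker = "SNP97.4")
#> SNP97.4: f = 9/10 = 0.900 (95% CrI 0.587-0.977), P = 0.01074 (one-tailed)

# population-scale minimum rate: 8 events, 125 generations, 10 lineages
mr <- min_rate(8, 125, 10)
#> minimum recombination rate: 8/(125 x 10) = 0.64% per meiosis
rate_to_cm_per_mb(mr$rate, 110000)
#> 5.8 cM/Mb over 110 kb

# simulate a distal-scale assay and recover its morphology
pos <- seq(0, 2600, by = 60)
mk  <- marker_map(paste0("g", seq_along(pos)), pos,
                  rep("A", length(pos)), rep("G", length(pos)))
sim <- simulate_sperm_molecules(mk, "full", rf = 0.002, centre = 1300,
                                sigma = 330, n_sperm = 76800, seed = 1)
calls <- do.call(rbind, lapply(sim$molecules, classify_molecules))
fit_normal(calls, mk, N = 76800)
#> hotspot_fit: centre 1333 bp, sigma 334 bp, 95% width 1310 bp, peak 241 cM/Mb (155 events, RSS 0.0028)
```

The first block turns the published molecule counts into point estimates,
intervals and a two-donor contrast; the last block shows that a simulated
hotspot with a 330-bp sigma (a ~1.3-kb 95% width) is recovered from the
inter-marker breakpoint intervals alone.

A YAML-driven orchestration (`run_pipeline()`, with a thin CLI wrapper in
`inst/scripts/eparscan.R`) chains the stages and writes JSON outputs plus a
run manifest; see `inst/extdata/example_config.yaml`.

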