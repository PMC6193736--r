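test_that("|D'| matches hand-computed two-locus gamete arithmetic", {
  # 20 haplotypes: 7 AB, 5 Ab, 3 aB, 5 ab -> pA=0.6, pB=0.5, pAB=0.35
  haps <- c(rep("AC", 7), rep("AT", 5), rep("GC", 3), rep("GT", 5))
  panel <- fix_panel(haps, ref = c("A", "C"), alt = c("G", "T"))
  ldm <- dprime_matrix(panel, maf_min = 0.2)
  # D = 0.35 - 0.30 = 0.05; Dmax = min(0.6*0.5, 0.4*0.5) = 0.2
  expect_equal(ldm$dprime[1, 2], 0.25)
  expect_equal(diag(ldm$dprime), c(m1 = 1, m2 = 1))
  expect_equal(ldm$dprime, t(ldm$dprime))
})

test_that("|D'| is 1 with at most three observed gamete classes", {
  combos <- list(c(8, 6, 6, 0), c(10, 5, 0, 5), c(12, 0, 4, 4), c(9, 9, 0, 0))
  for (cnt in combos) {
    haps <- rep(c("AC", "AT", "GC", "GT"), cnt)
    if (length(unique(substr(haps, 1, 1))) < 2 ||
        length(unique(substr(haps, 2, 2))) < 2) next
    panel <- fix_panel(haps, ref = c("A", "C"), alt = c("G", "T"))
    ldm <- dprime_matrix(panel, maf_min = 0.05)
    if (length(ldm$ids) == 2)
      expect_equal(ldm$dprime[1, 2], 1)
  }
  # complete LD construction
  panel <- fix_panel(c(rep("AC", 10), rep("GT", 10)),
                     ref = c("A", "C"), alt = c("G", "T"))
  expect_equal(dprime_matrix(panel, 0.2)$dprime[1, 2], 1)
  # independence frequencies -> 0
  panel0 <- fix_panel(c(rep("AC", 5), rep("AT", 5), rep("GC", 5), rep("GT", 5)),
                      ref = c("A", "C"), alt = c("G", "T"))
  expect_equal(dprime_matrix(panel0, 0.2)$dprime[1, 2], 0)
})

test_that("|D'| is invariant under allele-label swapping", {
  haps <- c(rep("AC", 7), rep("AT", 5), rep("GC", 3), rep("GT", 5))
  p1 <- fix_panel(haps, ref = c("A", "C"), alt = c("G", "T"))
  p2 <- fix_panel(haps, ref = c("G", "C"), alt = c("A", "T"))  # swap marker 1
  p3 <- fix_panel(haps, ref = c("A", "T"), alt = c("G", "C"))  # swap marker 2
  d1 <- dprime_matrix(p1, 0.2)$dprime[1, 2]
  expect_equal(dprime_matrix(p2, 0.2)$dprime[1, 2], d1)
  expect_equal(dprime_matrix(p3, 0.2)$dprime[1, 2], d1)
})

test_that("MAF filtering and zero-recombination panels behave as expected", {
  # MAF 0.1 marker dropped at the 0.2 threshold
  haps <- c(rep("AC", 18), rep("AT", 1), rep("GT", 1))
  panel <- fix_panel(haps, ref = c("A", "C"), alt = c("G", "T"))
  ldm <- dprime_matrix(panel, maf_min = 0.2)
  expect_equal(length(ldm$ids), 0)
  # a panel simulated without recombination is in complete LD throughout
  sim <- simulate_x_panel(60, 12, mixing_proportion = 0, seed = 31)
  ldm2 <- dprime_matrix(sim$panel, 0.2)
  off <- ldm2$dprime[upper.tri(ldm2$dprime)]
  expect_true(all(off == 1))
})

test_that("the X-chromosome HWE filter combines female HWE and sex-frequency tests", {
  # exact HWE and equal frequencies -> retained
  fem <- c(rep("AA", 25), rep("AG", 50), rep("GG", 25))
  hapstr <- c(rep("A", 50), rep("G", 50),
              unlist(strsplit(fem, "")))
  panel <- fix_panel(hapstr, ref = "A", alt = "G", n_males = 100)
  res <- x_hwe_filter(panel, alpha = 0.05)
  expect_equal(res$retained, "m1")
  expect_lt(res$stats$chisq, 1e-9)
  # total heterozygote excess -> removed (female HWE chi-square = n)
  fem2 <- rep("AG", 100)
  panel2 <- fix_panel(c(rep("A", 50), rep("G", 50), unlist(strsplit(fem2, ""))),
                      ref = "A", alt = "G", n_males = 100)
  res2 <- x_hwe_filter(panel2, alpha = 0.05)
  expect_equal(length(res2$retained), 0)
  expect_gte(res2$stats$chisq, 100)
  # alpha = 0 retains everything
  expect_equal(x_hwe_filter(panel2, alpha = 0)$retained, "m1")
  # undefined without females
  males_only <- fix_panel(c(rep("A", 4), rep("G", 4)), ref = "A", alt = "G",
                          n_males = 8)
  expect_error(x_hwe_filter(males_only), "females")
})

test_that("LD breakdown is called exactly at a block junction", {
  # two perfect-LD blocks of 6 markers joined at independence
  set.seed(10)
  left <- sample(0:1, 40, replace = TRUE)
  right <- sample(0:1, 40, replace = TRUE)
  haps <- vapply(1:40, function(i) {
    paste0(paste(rep(c("A", "G")[left[i] + 1], 6), collapse = ""),
           paste(rep(c("A", "G")[right[i] + 1], 6), collapse = ""))
  }, character(1))
  panel <- fix_panel(haps, ref = rep("A", 12), alt = rep("G", 12))
  ldm <- dprime_matrix(panel, 0.15)
  br <- ld_breakdown_regions(ldm, window_markers = 4, threshold = 0.5)
  expect_equal(nrow(br), 1)
  expect_true(br$start <= ldm$pos[6] && br$end >= ldm$pos[7])
  # uniform complete LD -> no breakdown intervals
  panel1 <- fix_panel(c(rep(paste(rep("A", 12), collapse = ""), 20),
                        rep(paste(rep("G", 12), collapse = ""), 20)),
                      ref = rep("A", 12), alt = rep("G", 12))
  ldm1 <- dprime_matrix(panel1, 0.2)
  expect_equal(nrow(ld_breakdown_regions(ldm1, 4, 0.5)), 0)
  # too few markers
  expect_error(ld_breakdown_regions(dprime_matrix(panel1, 0.2), 10, 0.5),
               "at least")
})

test_that("a simulated hotspot is localized in at least 90% of 50 seeds", {
  hits <- 0
  for (s in 1:50) {
    sim <- simulate_x_panel(100, 24, hotspot_positions = 5750,
                            mixing_proportion = 0.5, n_males = 20, seed = s)
    ldm <- dprime_matrix(sim$panel, 0.2)
    br <- ld_breakdown_regions(ldm, 4, 0.5)
    if (nrow(br) > 0 && any(br$start <= 5750 & br$end >= 5750)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("overlap counting agrees with a quadratic scan", {
  a0 <- genomic_intervals("chrX", c(0, 100), c(50, 150), c("x", "y"))
  b0 <- genomic_intervals("chrX", c(60, 200), c(90, 250), c("p", "q"))
  oc <- overlap_counts(a0, b0)
  expect_equal(c(oc$n_ld_overlapping, oc$n_dsb_overlapping), c(0, 0))
  oc2 <- overlap_counts(a0, a0)
  expect_equal(c(oc2$n_ld_overlapping, oc2$n_dsb_overlapping), c(2, 2))
  set.seed(77)
  for (rep in 1:10) {
    s1 <- sort(sample.int(10000, 8)); s2 <- sort(sample.int(10000, 6))
    a <- genomic_intervals("chrX", s1, s1 + sample.int(800, 8))
    b <- genomic_intervals("chrX", s2, s2 + sample.int(800, 6))
    oc <- overlap_counts(a, b)
    expect_equal(c(oc$n_ld_overlapping, oc$n_dsb_overlapping),
                 unname(oracle_overlap(a, b)))
  }
})

test_that("EM gamete frequencies recover phased truth from genotypes", {
  set.seed(123)
  freqs <- c(AB = 0.45, Ab = 0.15, aB = 0.1, ab = 0.3)
  g <- t(stats::rmultinom(400, 2, freqs))
  g1 <- 2 - (g[, 3] + g[, 4])  # copies of A
  g2 <- 2 - (g[, 2] + g[, 4])  # copies of B
  # genotype dosages lose phase only in double heterozygotes
  est <- em_gamete_frequencies(g1, g2)
  expect_equal(unname(est), unname(freqs), tolerance = 0.06)
  expect_equal(sum(est), 1, tolerance = 1e-8)
  # unambiguous case is exact: no double heterozygotes
  est2 <- em_gamete_frequencies(c(2, 2, 0, 0), c(2, 0, 2, 0))
  expect_equal(unname(est2), c(0.25, 0.25, 0.25, 0.25))
})
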