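test_that("generators are deterministic given (parameters, seed)", {
  mk <- fix_map()
  a <- simulate_sperm_molecules(mk, "half", rf = 0.01, centre = 1500,
                                sigma = 400, nco_fraction = 0.4,
                                n_sperm = 5000, seed = 17)
  b <- simulate_sperm_molecules(mk, "half", rf = 0.01, centre = 1500,
                                sigma = 400, nco_fraction = 0.4,
                                n_sperm = 5000, seed = 17)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  p1 <- simulate_x_panel(30, 10, hotspot_positions = 2250,
                         mixing_proportion = 0.5, seed = 17)
  p2 <- simulate_x_panel(30, 10, hotspot_positions = 2250,
                         mixing_proportion = 0.5, seed = 17)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  part <- define_blocks(p1$panel$markers, genomic_intervals("chrX", 2200, 2400))
  g1 <- simulate_epar_genealogy(5, 50, x_panel = p1$panel,
                                block_partition = part, seed = 17)
  g2 <- simulate_epar_genealogy(5, 50, x_panel = p1$panel,
                                block_partition = part, seed = 17)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
})

test_that("degenerate generator inputs are rejected or yield empty output", {
  mk <- fix_map()
  z <- simulate_sperm_molecules(mk, "full", rf = 0, centre = 1500, sigma = 300,
                                n_sperm = 10000, seed = 1)
  expect_equal(z$truth$params$n_recombinants, 0)
  expect_equal(nrow(z$molecules[["1"]]$alleles) + nrow(z$molecules[["2"]]$alleles), 0)
  expect_error(simulate_sperm_molecules(mk, "full", rf = 0.01, centre = 1500,
                                        sigma = 0, n_sperm = 100), "sigma")
  expect_error(simulate_sperm_molecules(mk, "full", rf = 0.01, centre = 9999,
                                        sigma = 300, n_sperm = 100), "span")
  expect_error(simulate_x_panel(10, 5, mixing_proportion = 1.5), "mixing")
  expect_error(simulate_x_panel(9, 5, n_males = 2), "pair up")
})

test_that("pool structure partitions the typed molecules", {
  pos <- seq(0, 3000, by = 300)
  mk <- marker_map(paste0("g", seq_along(pos)), pos,
                   rep("A", length(pos)), rep("G", length(pos)))
  sim <- simulate_sperm_molecules(mk, "full", rf = 0.01, centre = 1500,
                                  sigma = 400, n_sperm = 10000,
                                  pool_size = 5, seed = 3)
  ms <- sim$molecules[["1"]]
  expect_equal(length(ms$pools), nrow(ms$alleles))
  expect_true(all(table(ms$pools) <= 5))
})

test_that("estimated RF covers the simulated truth at nominal rates", {
  pos <- seq(0, 3000, by = 150)
  mk <- marker_map(paste0("g", seq_along(pos)), pos,
                   rep("A", length(pos)), rep("G", length(pos)))
  cover <- vapply(1:200, function(s) {
    sim <- simulate_sperm_molecules(mk, "full", rf = 0.002, centre = 1500,
                                    sigma = 330, n_sperm = 76800,
                                    seed = 5000 + s)
    calls <- do.call(rbind, lapply(sim$molecules, classify_molecules))
    e <- estimate_rf(sum(calls$class == "CO"), 76800)
    e$ci_low_pct <= 0.2 && 0.2 <= e$ci_high_pct
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("transmission bias is recovered within its credible interval", {
  pos <- seq(0, 3000, by = 150)
  mk <- marker_map(paste0("g", seq_along(pos)), pos,
                   rep("A", length(pos)), rep("G", length(pos)))
  cover <- vapply(1:200, function(s) {
    sim <- simulate_sperm_molecules(mk, "full", rf = 0.002, centre = 1500,
                                    sigma = 330, f_bias = 0.62,
                                    n_sperm = 76800, seed = 6000 + s)
    calls <- do.call(rbind, lapply(sim$molecules, classify_molecules))
    k <- sum(calls$orientation == "1" & calls$class == "CO")
    n <- sum(calls$class == "CO")
    ci <- credible_interval(k, n)
    ci[1] <= 0.62 && 0.62 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("panel generator edge cases produce the documented LD structure", {
  sim0 <- simulate_x_panel(50, 10, hotspot_positions = 2250,
                           mixing_proportion = 0, seed = 8)
  d0 <- dprime_matrix(sim0$panel, 0.2)$dprime
  expect_true(all(d0[upper.tri(d0)] == 1))
  # truth record carries lineages and parameters
  expect_equal(sim0$truth$params$mixing_proportion, 0)
  expect_equal(dim(sim0$truth$params$lineages), c(50, 2))
})

test_that("genealogies without crossovers or mutations are static", {
  sim <- simulate_x_panel(30, 10, hotspot_positions = 2250,
                          mixing_proportion = 0.5, seed = 12)
  part <- define_blocks(sim$panel$markers, genomic_intervals("chrX", 2200, 2400))
  gen <- simulate_epar_genealogy(10, 125, mu = 0.002, co_rate = 0,
                                 x_panel = sim$panel, block_partition = part,
                                 seed = 13)
  expect_equal(min_recombination_events(gen$haplotypes), 0)
  expect_equal(gen$truth$params$n_events_total, 0)
  expect_true(all(gen$haplotypes$strings ==
                    matrix(gen$truth$params$founder_blocks, 10, 2, byrow = TRUE)))
  # effectively mutation-free loci leave every lineage at the founder -> t = 0
  gen2 <- simulate_epar_genealogy(10, 125, mu = 1e-9, co_rate = 0,
                                  x_panel = sim$panel, block_partition = part,
                                  seed = 14)
  expect_equal(asd_tmrca(gen2$strs,
                         founder = gen2$truth$params$founder_repeats)$t_generations,
               0)
})

test_that("the full sperm pipeline recovers rf, centre, sigma and bias jointly", {
  pos <- seq(0, 2600, by = 60)
  mk <- marker_map(paste0("g", seq_along(pos)), pos,
                   rep("A", length(pos)), rep("G", length(pos)))
  ok_rf <- logical(100); ok_mu <- logical(100); ok_f <- logical(100)
  for (s in 1:100) {
    sim <- simulate_sperm_molecules(mk, "full", rf = 0.002, centre = 1300,
                                    sigma = 330, f_bias = 0.62,
                                    n_sperm = 76800, seed = 40000 + s)
    calls <- do.call(rbind, lapply(sim$molecules, classify_molecules))
    k <- sum(calls$class == "CO")
    e <- estimate_rf(k, 76800)
    ok_rf[s] <- e$ci_low_pct <= 0.2 && 0.2 <= e$ci_high_pct
    fit <- fit_normal(calls, mk, N = 76800)
    ok_mu[s] <- abs(fit$centre - 1300) < 0.3 * 330
    k1 <- sum(calls$orientation == "1" & calls$class == "CO")
    ci <- credible_interval(k1, k)
    ok_f[s] <- ci[1] <= 0.62 && 0.62 <= ci[2]
  }
  expect_gte(mean(ok_rf), 0.93)
  expect_gte(mean(ok_f), 0.93)
  expect_gte(mean(ok_mu), 0.9)
})
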