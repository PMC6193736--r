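ten_markers <- function() {
  data.frame(id = paste0("m", 1:10), pos = seq(0L, 9000L, by = 1000L),
             stringsAsFactors = FALSE)
}

chs_from_strings <- function(strings, partition = NULL) {
  strings <- as.matrix(strings)
  structure(list(strings = strings,
                 samples = rownames(strings) %||% paste0("h", seq_len(nrow(strings))),
                 lineage = rep(NA_character_, nrow(strings)),
                 partition = partition),
            class = "compound_haplotype_set")
}

test_that("blocks are the maximal marker runs outside DSB clusters", {
  mk <- ten_markers()
  # one cluster covering markers 4-6 (pos 3000-5000) -> blocks of 3 and 4
  cl <- genomic_intervals("chrX", 2500, 5500, "dsbA")
  part <- define_blocks(mk, cl)
  expect_equal(nrow(part$blocks), 2)
  expect_equal(unname(vapply(part$marker_ids, length, integer(1))), c(3, 4))
  expect_equal(part$marker_ids[[1]], paste0("m", 1:3))
  expect_equal(part$blocks$index, 1:2)
  # no clusters -> a single block
  part1 <- define_blocks(mk, genomic_intervals())
  expect_equal(nrow(part1$blocks), 1)
  expect_equal(length(part1$marker_ids[[1]]), 10)
  # clusters covering everything -> error
  expect_error(define_blocks(mk, genomic_intervals("chrX", 0, 10000)),
               "no markers")
  # idempotence: partitioning the retained markers again changes nothing
  part2 <- define_blocks(part$markers[, c("id", "pos")], cl)
  expect_equal(part2$marker_ids, part$marker_ids)
  expect_equal(part2$blocks, part$blocks)
})

test_that("the consensus is the modal compound haplotype, ties flagged", {
  base <- c("ACG", "TT", "GGGA")
  strings <- do.call(rbind, c(list(base, base),
                              lapply(1:8, function(i) {
                                s <- base; s[1 + i %% 3] <- paste0(
                                  substr(s[1 + i %% 3], 1, nchar(s[1 + i %% 3]) - 1),
                                  c("A", "C", "G", "T")[1 + (i %% 4)])
                                s
                              })))
  # force the 8 others distinct from base and each other where collisions arise
  strings[3:10, 1] <- paste0("AC", c("A", "C", "T", "A", "C", "T", "A", "C"))
  strings[3:10, 2] <- paste0("T", c("A", "A", "A", "C", "C", "C", "G", "G"))
  chs <- chs_from_strings(strings)
  cons <- consensus_haplotype(chs)
  expect_equal(cons$multiplicity, 2)
  expect_false(cons$ambiguous)
  expect_equal(unname(cons$consensus), base)
  # all identical
  all_same <- chs_from_strings(do.call(rbind, replicate(5, base, simplify = FALSE)))
  expect_equal(consensus_haplotype(all_same)$multiplicity, 5)
  # tie between two doubletons
  other <- c("AAA", "TT", "GGGA")
  tied <- chs_from_strings(do.call(rbind, list(base, base, other, other)))
  expect_true(consensus_haplotype(tied)$ambiguous)
  expect_equal(length(consensus_haplotype(tied)$candidates), 2)
  # all unique -> instructive error
  uniq <- chs_from_strings(rbind(base, other, c("CCC", "TT", "GGGA")))
  expect_error(consensus_haplotype(uniq), "manually")
})

test_that("single-crossover explanations place the breakpoint and incoming side", {
  consensus <- paste0("B", 1:9)
  # differs in blocks 1-2 -> breakpoint after block 2, incoming blocks 1-2
  hap <- consensus; hap[1:2] <- c("X1", "X2")
  ex <- single_crossover_explanation(hap, consensus)
  expect_true(ex$event)
  expect_equal(ex$breakpoint_after_block, 2)
  expect_equal(ex$incoming, c("X1", "X2"))
  expect_equal(ex$blocks_differing, 1:2)
  # differs in block 7 only -> incoming spans blocks 1-7 (1-6 matching)
  hap2 <- consensus; hap2[7] <- "X7"
  ex2 <- single_crossover_explanation(hap2, consensus)
  expect_equal(ex2$breakpoint_after_block, 7)
  expect_equal(length(ex2$incoming), 7)
  expect_equal(ex2$incoming[1:6], consensus[1:6])
  expect_equal(unname(ex2$snp_differences), 1)
  # identical -> no event
  ex3 <- single_crossover_explanation(consensus, consensus)
  expect_false(ex3$event)
  expect_error(single_crossover_explanation(consensus[1:3], consensus),
               "same blocks")
})

test_that("explanations always leave proximal blocks equal to consensus", {
  set.seed(42)
  consensus <- replicate(9, paste(sample(c("A", "G"), 4, TRUE), collapse = ""))
  for (i in 1:50) {
    hap <- consensus
    nd <- sample(0:9, 1)
    if (nd > 0) {
      idx <- sample(9, nd)
      hap[idx] <- vapply(hap[idx], function(s) {
        p <- sample(4, 1)
        substr(s, p, p) <- setdiff(c("A", "G", "C"), substr(s, p, p))[1]
        s
      }, character(1))
    }
    ex <- single_crossover_explanation(hap, consensus)
    if (!ex$event) { expect_equal(hap, consensus); next }
    b <- ex$breakpoint_after_block
    if (b < 9) expect_equal(hap[(b + 1):9], consensus[(b + 1):9])
    expect_true(any(hap[seq_len(b)] != consensus[seq_len(b)]))
    expect_equal(ex$incoming, hap[seq_len(b)])
  }
})

test_that("haplotype matching reports carriers whole and per block", {
  panel <- chs_from_strings(rbind(h1 = c("AA", "CC", "GG"),
                                  h2 = c("AA", "CT", "GG"),
                                  h3 = c("TA", "CC", "GA")))
  hit <- match_haplotypes(c("AA", "CT", "GG"), panel, scope = "full")
  expect_equal(hit$matches, "h2")
  miss <- match_haplotypes(c("TT", "TT", "TT"), panel, scope = "full")
  expect_equal(miss$n, 0)
  per <- match_haplotypes(c("TT", "TT", "GA"), panel, scope = "per_block")
  expect_equal(per$n_matches, c(0, 0, 1))
  expect_equal(attr(per, "matches")[[3]], "h3")
  expect_error(match_haplotypes(c("AA", "CC"), panel), "different block")
})

test_that("minimum event counts equal distinct haplotypes minus one", {
  base <- c("AC", "GT")
  # 10 haplotypes, 9 distinct -> 8 events minimum
  strings <- rbind(base, base,
                   t(vapply(1:8, function(i) c(paste0("V", i), "GT"),
                            character(2))))
  expect_equal(min_recombination_events(chs_from_strings(strings)), 8)
  same <- chs_from_strings(do.call(rbind, replicate(6, base, simplify = FALSE)))
  expect_equal(min_recombination_events(same), 0)
  distinct <- chs_from_strings(cbind(paste0("X", 1:7), "GT"))
  expect_equal(min_recombination_events(distinct), 6)
})

test_that("the minimum count never exceeds the simulated event count", {
  sim <- simulate_x_panel(40, 20, hotspot_positions = c(2750, 5750),
                          mixing_proportion = 0.4, seed = 400)
  dsb <- genomic_intervals("chrX", c(2600, 5600), c(2900, 5900))
  part <- define_blocks(sim$panel$markers, dsb)
  for (s in 1:100) {
    gen <- simulate_epar_genealogy(n_lineages = 10, t_generations = 125,
                                   mu = 0.002, co_rate = 0.0064,
                                   x_panel = sim$panel, block_partition = part,
                                   seed = 9000 + s)
    expect_lte(min_recombination_events(gen$haplotypes),
               gen$truth$params$n_events_total)
  }
  for (s in 1:100) {
    gen <- simulate_epar_genealogy(n_lineages = 8, t_generations = 80,
                                   mu = 0.002, co_rate = 0.01,
                                   x_panel = sim$panel, block_partition = part,
                                   topology = "bifurcating", seed = 12000 + s)
    expect_lte(min_recombination_events(gen$haplotypes),
               gen$truth$params$n_events_total)
  }
})
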