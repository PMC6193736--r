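# Generators that reproduce the statistical structure each analysis stage
# assumes, with truth records for parameter-recovery testing. All
# generators take one seed; a single R stream is seeded once per call and
# substreams are drawn in a fixed documented order, so identical
# (parameters, seed) yield identical output.

sim_truth <- function(scenario, seed, params) {
  structure(list(scenario = scenario, seed = seed, params = params),
            class = "sim_truth")
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate typed sperm molecules from a Gaussian hotspot
#'
#' Emulates reciprocal full or half sperm assays at a single hotspot. The
#' recombinant count is Binomial(`n_sperm`, `rf`); each recombinant is a
#' crossover with probability `1 - nco_fraction` (breakpoint ~
#' Normal(`centre`, `sigma`), truncated to the marker span and assigned to
#' its inter-marker interval) and otherwise a non-crossover (tract centre
#' from the same Gaussian, tract length geometric with mean `tract_mean`).
#' The orientation (which parental haplotype carries the distal side, or
#' which haplotype is amplified in a half assay) is drawn with probability
#' `f_bias` for orientation 1, modelling transmission distortion.
#' Recombinants whose flipped-marker set is empty are undetectable by the
#' assay and are recorded in the truth but omitted from the molecule sets.
#'
#' @param markers a [marker_map()].
#' @param design `"full"` or `"half"`.
#' @param rf true per-sperm recombination fraction.
#' @param centre,sigma hotspot centre and width parameter (bp); `sigma > 0`.
#' @param f_bias probability a recombinant arises in orientation 1.
#' @param nco_fraction fraction of recombinants that are NCOs.
#' @param tract_mean mean NCO tract length (bp).
#' @param n_sperm total sperm screened (split evenly over orientations).
#' @param pool_size optional molecules per pool.
#' @param universal_end for half assays, `"distal"` or `"proximal"`.
#' @param seed integer seed.
#' @return List with `molecules` (named list of [molecule_set()]s, one per
#'   orientation) and `truth` (a `sim_truth` whose `$params$events` data
#'   frame carries per-recombinant type, position, orientation, the
#'   expected observable class and detectability).
#' @export
simulate_sperm_molecules <- function(markers, design = c("full", "half"), rf,
                                     centre, sigma, f_bias = 0.5,
                                     nco_fraction = 0, tract_mean = 300,
                                     n_sperm, pool_size = NULL,
                                     universal_end = "proximal", seed = NULL) {
  design <- match.arg(design)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (centre < min(markers$pos) || centre > max(markers$pos))
    stop("centre must lie within the marker span", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(markers)
  pos <- markers$pos
  span <- range(pos)
  n_rec <- stats::rbinom(1, n_sperm, rf)
  orient <- ifelse(stats::runif(n_rec) < f_bias, "1", "2")
  is_co <- stats::runif(n_rec) >= nco_fraction
  x <- rnorm_trunc(n_rec, centre, sigma, span[1], span[2])
  tract_len <- ifelse(is_co, NA_real_,
                      stats::rgeom(n_rec, 1 / max(tract_mean, 1)) + 1)
  rows <- vector("list", n_rec)
  flip_term <- function(flip) {
    # expected observable class for a half assay given flipped markers
    f <- which(flip)
    if (!length(f)) return(c(NA, "undetected"))
    if (min(f) == 1) return(c(TRUE, "unscorable"))  # touches the ASP end
    if (max(f) == m) {
      if (length(f) == 1) c(TRUE, "terminal_ambiguous") else c(TRUE, "CO")
    } else c(TRUE, "NCO")
  }
  alleles_list <- list(); orient_list <- character(); truth_rows <- list()
  for (i in seq_len(n_rec)) {
    if (design == "full") {
      flip <- pos >= x[i]            # proximal side carries the other hap
      detected <- any(flip) && !all(flip)
      exp_class <- if (detected) "CO" else "undetected"
    } else {
      if (is_co[i]) {
        flip <- pos >= x[i]
        if (identical(universal_end, "distal")) flip <- pos < x[i]
      } else {
        lo <- x[i] - tract_len[i] / 2; hi <- x[i] + tract_len[i] / 2
        flip <- pos >= lo & pos <= hi
      }
      # orient terminal test to the universal end
      flip_o <- if (identical(universal_end, "distal")) rev(flip) else flip
      ft <- flip_term(flip_o)
      detected <- !identical(ft[2], "undetected")
      exp_class <- ft[2]
    }
    truth_rows[[i]] <- data.frame(
      molecule = NA_character_, orientation = orient[i],
      type = if (is_co[i]) "CO" else "NCO", position = x[i],
      tract_len = tract_len[i], detected = detected,
      expected_class = exp_class, stringsAsFactors = FALSE)
    if (!detected) next
    if (design == "full") {
      hapvec <- if (orient[i] == "1") ifelse(flip, "B", "A") else
        ifelse(flip, "A", "B")
    } else {
      sel <- if (orient[i] == "1") "A" else "B"
      opp <- setdiff(c("A", "B"), sel)
      hapvec <- ifelse(flip, opp, sel)
    }
    alleles_list[[length(alleles_list) + 1]] <-
      ifelse(hapvec == "A", markers$allele_a, markers$allele_b)
    orient_list[length(orient_list) + 1] <- orient[i]
    truth_rows[[i]]$molecule <- paste0("sim", length(alleles_list))
  }
  truth_df <- if (n_rec) do.call(rbind, truth_rows) else
    data.frame(molecule = character(), orientation = character(),
               type = character(), position = numeric(), tract_len = numeric(),
               detected = logical(), expected_class = character())
  half_n <- c(ceiling(n_sperm / 2), floor(n_sperm / 2))
  mol_sets <- lapply(c("1", "2"), function(o) {
    sel_rows <- which(orient_list == o)
    al <- if (length(sel_rows)) {
      do.call(rbind, alleles_list[sel_rows])
    } else matrix(character(0), 0, m)
    if (length(sel_rows))
      rownames(al) <- truth_df$molecule[truth_df$detected][sel_rows]
    pools <- if (!is.null(pool_size) && length(sel_rows)) {
      paste0("p", (seq_len(nrow(al)) - 1) %/% pool_size + 1)
    } else NULL
    molecule_set(markers, al, design = design, orientation = o,
                 selected_hap = if (design == "half") c("A", "B")[as.integer(o)],
                 universal_end = if (design == "half") universal_end,
                 n_sperm = half_n[as.integer(o)], pools = pools)
  })
  names(mol_sets) <- c("1", "2")
  list(molecules = mol_sets,
       truth = sim_truth("sperm", seed,
                         list(rf = rf, centre = centre, sigma = sigma,
                              f_bias = f_bias, nco_fraction = nco_fraction,
                              tract_mean = tract_mean, n_sperm = n_sperm,
                              n_recombinants = n_rec, events = truth_df)))
}

#' Simulate a phased X-chromosomal haplotype panel with hotspot LD structure
#'
#' Two ancestral haplotypes segregate; haplotypes copy one ancestral lineage
#' within each inter-hotspot segment and may switch lineage only at hotspot
#' positions, each switch occurring with probability `mixing_proportion`.
#' This yields complete LD (|D'| = 1) within segments and LD breakdown at
#' hotspots. Segment lineage frequencies are resampled (up to 50 draws) to
#' stay within [0.25, 0.75] so that minor allele frequencies clear a
#' 0.2 MAF filter.
#'
#' @param n_haplotypes total haplotype rows; the first `n_males` are single
#'   male X's, the remainder (which must be even) are paired into females.
#' @param n_markers number of SNPs.
#' @param hotspot_positions bp positions (0-based) where lineage switching
#'   is allowed; must lie within the marker span.
#' @param mixing_proportion per-hotspot probability of re-drawing the
#'   lineage; 0 gives panel-wide complete LD.
#' @param positions optional explicit marker positions; default
#'   `(0:(n_markers-1)) * spacing`.
#' @param spacing default marker spacing in bp.
#' @param n_males haplotypes assigned to male samples.
#' @param population population tag.
#' @param seed integer seed.
#' @return List with `panel` (a [haplotype_panel()]) and `truth` (lineage
#'   matrix and parameters).
#' @export
simulate_x_panel <- function(n_haplotypes, n_markers,
                             hotspot_positions = numeric(),
                             mixing_proportion = 0, positions = NULL,
                             spacing = 500, n_males = 0,
                             population = "SIM", seed = NULL) {
  if (mixing_proportion < 0 || mixing_proportion > 1)
    stop("mixing_proportion must lie in [0, 1]", call. = FALSE)
  if ((n_haplotypes - n_males) %% 2 != 0)
    stop("female haplotypes (n_haplotypes - n_males) must pair up evenly",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- (seq_len(n_markers) - 1L) * spacing
  if (length(hotspot_positions) &&
      (min(hotspot_positions) <= min(positions) ||
       max(hotspot_positions) >= max(positions)))
    stop("hotspot positions must lie strictly within the marker span",
         call. = FALSE)
  seg <- findInterval(positions, sort(hotspot_positions)) + 1L
  n_seg <- max(seg)
  draw_lineage <- function() {
    lin <- matrix(0L, n_haplotypes, n_seg)
    lin[, 1] <- stats::rbinom(n_haplotypes, 1, 0.5)
    if (n_seg > 1) for (s in 2:n_seg) {
      # a mixed haplotype is a visible recombinant: it carries the opposite
      # ancestral lineage beyond the hotspot, so cross-hotspot |D'| decays
      # as |1 - 2*mixing| while within-segment |D'| stays 1
      switch_ <- stats::runif(n_haplotypes) < mixing_proportion
      lin[, s] <- ifelse(switch_, 1L - lin[, s - 1], lin[, s - 1])
    }
    lin
  }
  lin <- draw_lineage()
  for (try in seq_len(50)) {
    freq <- colMeans(lin)
    if (all(freq >= 0.25 & freq <= 0.75)) break
    lin <- draw_lineage()
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  alleles <- matrix(NA_character_, n_haplotypes, n_markers)
  for (j in seq_len(n_markers)) {
    alleles[, j] <- ifelse(lin[, seg[j]] == 1L, alt[j], ref[j])
  }
  n_fem <- (n_haplotypes - n_males) / 2
  samples <- rbind(
    if (n_males) data.frame(sample = paste0("M", seq_len(n_males)),
                            sex = "male", hap_index = 1L),
    if (n_fem) data.frame(sample = rep(paste0("F", seq_len(n_fem)), each = 2),
                          sex = "female", hap_index = rep(1:2, n_fem)))
  markers <- data.frame(id = paste0("m", seq_len(n_markers)), pos = positions,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  panel <- haplotype_panel(markers, samples, alleles, population)
  list(panel = panel,
       truth = sim_truth("x_panel", seed,
                         list(hotspot_positions = sort(hotspot_positions),
                              mixing_proportion = mixing_proportion,
                              lineages = lin, segments = seg)))
}

#' Simulate a Y-lineage genealogy with STR mutation and block crossovers
#'
#' Each lineage evolves `t_generations` from a founder. Y-STR loci mutate by
#' +/-1 repeat steps at rate `mu` per generation (stepwise mutation model);
#' with probability `co_rate` per generation a crossover replaces all blocks
#' distal of a uniformly drawn between-block breakpoint with the
#' corresponding blocks of a haplotype sampled from the X panel. The default
#' star topology has every lineage radiating independently from the founder,
#' matching the minimum-rate formula; the bifurcating option splits lineages
#' at random times so events can be shared by descent.
#'
#' @param n_lineages number of sampled Y lineages.
#' @param t_generations generations since the founder.
#' @param mu per-locus mutation rates: scalar (recycled over `n_loci` loci)
#'   or named vector.
#' @param n_loci number of STR loci when `mu` is scalar (default 23).
#' @param co_rate per-generation crossover probability.
#' @param x_panel a [haplotype_panel()] supplying incoming X haplotypes.
#' @param block_partition a [define_blocks()] partition consistent with the
#'   panel's markers.
#' @param founder_repeats founder repeat counts (default 16 at every locus).
#' @param topology `"star"` or `"bifurcating"`.
#' @param seed integer seed.
#' @return List with `strs` (an [str_haplotype_set()]), `haplotypes` (a
#'   [compound_haplotypes()] set for the lineages) and `truth` (including
#'   the total simulated crossover count `n_events_total`).
#' @export
simulate_epar_genealogy <- function(n_lineages = 10, t_generations = 125,
                                    mu = 0.002, n_loci = 23, co_rate = 0.0064,
                                    x_panel, block_partition,
                                    founder_repeats = NULL,
                                    topology = c("star", "bifurcating"),
                                    seed = NULL) {
  topology <- match.arg(topology)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(mu))) {
    if (length(mu) == 1) mu <- rep(mu, n_loci)
    names(mu) <- paste0("L", seq_along(mu))
  }
  L <- length(mu)
  if (is.null(founder_repeats)) founder_repeats <- rep(16L, L)
  founder_repeats <- stats::setNames(as.integer(founder_repeats), names(mu))
  panel_chs <- compound_haplotypes(x_panel, block_partition)
  k <- ncol(panel_chs$strings)
  founder_blocks <- panel_chs$strings[1, ]
  sample_incoming <- function() panel_chs$strings[
    sample.int(nrow(panel_chs$strings), 1), ]

  if (topology == "star") {
    n_mut <- matrix(stats::rbinom(n_lineages * L, t_generations,
                                  rep(mu, each = n_lineages)), n_lineages, L)
    net <- matrix(2L * stats::rbinom(n_lineages * L, as.vector(n_mut), 0.5) -
                    as.vector(n_mut), n_lineages, L)
    reps <- sweep(net, 2, founder_repeats, `+`)
    reps <- pmax(reps, 1L)
    blocks <- matrix(rep(founder_blocks, each = n_lineages), n_lineages, k)
    events <- list()
    for (i in seq_len(n_lineages)) {
      n_co <- stats::rbinom(1, t_generations, co_rate)
      if (n_co == 0) next
      for (e in seq_len(n_co)) {
        b <- if (k > 1) sample.int(k - 1, 1) else next
        inc <- sample_incoming()
        blocks[i, seq_len(b)] <- inc[seq_len(b)]
        events[[length(events) + 1]] <-
          data.frame(lineage = i, breakpoint_after_block = b)
      }
    }
  } else {
    # forward simulation with lineage splits at sorted random generations
    split_gen <- sort(sample.int(t_generations, n_lineages - 1, replace = TRUE))
    state_reps <- matrix(founder_repeats, 1, L, byrow = TRUE)
    state_blocks <- matrix(founder_blocks, 1, k, byrow = TRUE)
    events <- list()
    for (g in seq_len(t_generations)) {
      for (s in which(split_gen == g)) {
        src <- sample.int(nrow(state_reps), 1)
        state_reps <- rbind(state_reps, state_reps[src, ])
        state_blocks <- rbind(state_blocks, state_blocks[src, , drop = FALSE])
      }
      nl <- nrow(state_reps)
      mut <- matrix(stats::runif(nl * L) < rep(mu, each = nl), nl, L)
      step <- matrix(ifelse(stats::runif(nl * L) < 0.5, 1L, -1L), nl, L)
      state_reps <- pmax(state_reps + mut * step, 1L)
      co <- which(stats::runif(nl) < co_rate)
      for (i in co) {
        b <- if (k > 1) sample.int(k - 1, 1) else next
        inc <- sample_incoming()
        state_blocks[i, seq_len(b)] <- inc[seq_len(b)]
        events[[length(events) + 1]] <-
          data.frame(lineage = i, breakpoint_after_block = b, generation = g)
      }
    }
    # pad/truncate to n_lineages (splits with replacement can collide)
    while (nrow(state_reps) < n_lineages) {
      src <- sample.int(nrow(state_reps), 1)
      state_reps <- rbind(state_reps, state_reps[src, ])
      state_blocks <- rbind(state_blocks, state_blocks[src, , drop = FALSE])
    }
    reps <- state_reps[seq_len(n_lineages), , drop = FALSE]
    blocks <- state_blocks[seq_len(n_lineages), , drop = FALSE]
  }
  colnames(reps) <- names(mu)
  rownames(reps) <- paste0("lineage", seq_len(n_lineages))
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(lineage = integer(), breakpoint_after_block = integer())
  chs <- structure(list(strings = blocks,
                        samples = rownames(reps),
                        lineage = rep("I2a-sim", n_lineages),
                        partition = block_partition),
                   class = "compound_haplotype_set")
  rownames(chs$strings) <- rownames(reps)
  colnames(chs$strings) <- paste0("block", seq_len(k))
  list(strs = str_haplotype_set(reps, mu),
       haplotypes = chs,
       truth = sim_truth("genealogy", seed,
                         list(t_generations = t_generations, mu = mu,
                              co_rate = co_rate, topology = topology,
                              founder_repeats = founder_repeats,
                              founder_blocks = founder_blocks,
                              events = ev_df,
                              n_events_total = nrow(ev_df))))
}
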