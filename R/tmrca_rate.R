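# ASD-based TMRCA from Y-STR haplotypes, and conversion of minimum event
# counts into per-meiosis and per-Mb recombination rates.

#' TMRCA from Y-STR haplotypes by the ASD method
#'
#' Under the stepwise mutation model the average squared distance (ASD) of
#' repeat counts from the founder haplotype grows linearly with time:
#' `E[ASD_l] = mu_l * t`. Each locus therefore gives `t_l = ASD_l / mu_l`
#' generations; the point estimate is the mean over loci and the standard
#' error comes from a leave-one-locus-out jackknife (the per-locus averaging
#' and the jackknife are recorded in the output provenance). Bilocal markers
#' (e.g. DYS385a/b) are treated as two exchangeable columns: each sample's
#' pair is oriented to minimize its squared distance to the founder pair.
#'
#' @param strs an [str_haplotype_set()].
#' @param founder optional named integer vector of founder repeat counts;
#'   defaults to the per-locus modal repeat count (smallest mode on ties).
#' @param generation_time years per generation (default 31).
#' @return Object of class `tmrca_estimate`: `asd_per_locus`,
#'   `t_per_locus`, `t_generations`, `se_generations`, `t_years`,
#'   `se_years`, `generation_time`, `founder`, `n_excluded_calls`,
#'   `provenance`.
#' @export
asd_tmrca <- function(strs, founder = NULL, generation_time = 31) {
  reps <- strs$repeats
  loci <- colnames(reps)
  mu <- strs$mu
  if (any(mu <= 0)) stop("all loci need mutation rates > 0", call. = FALSE)
  if (is.null(founder)) {
    founder <- vapply(loci, function(l) {
      v <- reps[, l]; v <- v[!is.na(v)]
      tab <- table(v)
      as.integer(names(tab)[tab == max(tab)][1])
    }, integer(1))
  } else {
    miss <- setdiff(loci, names(founder))
    if (length(miss)) stop("founder lacks locus/loci: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    founder <- founder[loci]
  }
  # orient bilocal pairs to minimize squared distance to the founder pair
  if (!is.null(strs$bilocal)) {
    for (p in strs$bilocal) {
      fa <- founder[[p[1]]]; fb <- founder[[p[2]]]
      for (i in seq_len(nrow(reps))) {
        a <- reps[i, p[1]]; b <- reps[i, p[2]]
        if (anyNA(c(a, b))) next
        if ((a - fa)^2 + (b - fb)^2 > (b - fa)^2 + (a - fb)^2) {
          reps[i, p[1]] <- b; reps[i, p[2]] <- a
        }
      }
    }
  }
  n_excluded <- sum(is.na(reps))
  d2 <- sweep(reps, 2, founder)^2
  asd <- colMeans(d2, na.rm = TRUE)
  t_l <- asd / mu
  L <- length(t_l)
  t_hat <- mean(t_l)
  if (L > 1) {
    t_loo <- vapply(seq_len(L), function(i) mean(t_l[-i]), numeric(1))
    se <- sqrt((L - 1) / L * sum((t_loo - mean(t_loo))^2))
  } else se <- NA_real_
  structure(list(asd_per_locus = asd, t_per_locus = t_l,
                 t_generations = t_hat, se_generations = se,
                 t_years = t_hat * generation_time,
                 se_years = se * generation_time,
                 generation_time = generation_time, founder = founder,
                 n_excluded_calls = n_excluded,
                 provenance = list(estimator = "mean over loci of ASD_l/mu_l",
                                   se = "leave-one-locus-out jackknife")),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA: %.0f +/- %.0f yrs (%.1f generations at %g yrs/gen)\n",
              x$t_years, x$se_years, x$t_generations, x$generation_time))
  invisible(x)
}

#' Convert an age in years to generations
#'
#' @param years age in years.
#' @param generation_time years per generation (default 31).
#' @return Generations.
#' @export
generations_from_years <- function(years, generation_time = 31) {
  if (generation_time <= 0) stop("generation_time must be positive", call. = FALSE)
  years / generation_time
}

#' Minimum per-meiosis recombination rate from a star genealogy
#'
#' Divides the minimum event count by the total meioses sampled,
#' `generations * lineages`. This is a lower bound twice over: the event
#' count is a parsimony minimum, and a star genealogy (all lineages
#' radiating from the common ancestor) maximizes the meioses available.
#'
#' @param events minimum recombination event count (>= 0).
#' @param generations generations back to the common ancestor.
#' @param lineages number of sampled lineages.
#' @return Object of class `rate_summary`: `events`, `generations`,
#'   `lineages`, `rate` (fraction), `pct`.
#' @export
min_rate <- function(events, generations, lineages) {
  if (events < 0) stop("events must be >= 0", call. = FALSE)
  if (generations <= 0 || lineages <= 0)
    stop("generations and lineages must be positive", call. = FALSE)
  rate <- events / (generations * lineages)
  structure(list(events = events, generations = generations,
                 lineages = lineages, rate = rate, pct = 100 * rate),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("minimum recombination rate: %g/(%g x %g) = %.2f%% per meiosis\n",
              x$events, x$generations, x$lineages, x$pct))
  invisible(x)
}

#' Convert a per-meiosis rate into cM/Mb
#'
#' A rate of 1% over a region corresponds to 1 cM of genetic length, so
#' cM/Mb = `100 * rate / (region_length / 1e6)`.
#'
#' @param rate per-meiosis recombination fraction (0..1).
#' @param region_length physical length of the region in bp.
#' @return cM/Mb.
#' @export
rate_to_cm_per_mb <- function(rate, region_length) {
  if (region_length <= 0) stop("region_length must be positive", call. = FALSE)
  100 * rate / (region_length / 1e6)
}
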