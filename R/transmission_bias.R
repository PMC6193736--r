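# Transmission-distortion tests among reciprocal recombinants, Bayesian
# credible intervals, gametic ratios, and GC-bias testing of NCO tracts.

#' Exact binomial transmission-distortion test
#'
#' Tests whether `k` of `n` informative recombinants carrying the focal
#' allele departs from the 50:50 expectation for reciprocal events. The
#' one-tailed P is the upper tail `P(X >= k)`; the two-tailed P doubles the
#' smaller tail, capped at 1.
#'
#' @param k recombinants carrying the focal allele.
#' @param n informative recombinants.
#' @param tail `"two"` or `"one"`.
#' @param level credible-interval level for the accompanying interval.
#' @param marker optional marker id annotation.
#' @param focal_class optional focal-allele class annotation
#'   (strong/weak or purine/pyrimidine).
#' @return An object of class `transmission_result` with `k`, `n`, `f = k/n`,
#'   `ci` (95% equal-tailed Beta credible interval), `p_value`, `tail`.
#' @export
transmission_test <- function(k, n, tail = c("two", "one"), level = 0.95,
                              marker = NA_character_,
                              focal_class = NA_character_) {
  tail <- match.arg(tail)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  lower <- stats::pbinom(k, n, 0.5)                          # P(X <= k)
  p <- if (tail == "one") upper else min(1, 2 * min(lower, upper))
  structure(list(marker = marker, k = k, n = n, f = k / n,
                 ci = credible_interval(k, n, level),
                 p_value = p, tail = tail, focal_class = focal_class),
            class = "transmission_result")
}

#' @export
print.transmission_result <- function(x, ...) {
  cat(sprintf("%s: f = %d/%d = %.3f (95%% CrI %.3f-%.3f), P = %.4g (%s-tailed)\n",
              if (is.na(x$marker)) "transmission" else x$marker,
              x$k, x$n, x$f, x$ci[1], x$ci[2], x$p_value, x$tail))
  invisible(x)
}

#' Equal-tailed Bayesian credible interval for a transmission frequency
#'
#' Posterior is Beta(k+1, n-k+1) under a uniform Beta(1,1) prior; the
#' equal-tailed interval is used (not HPD) for reproducibility.
#'
#' @param k successes.
#' @param n trials.
#' @param level credible level in (0, 1).
#' @return Numeric length-2 vector (lower, upper).
#' @export
credible_interval <- function(k, n, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  a <- (1 - level) / 2
  stats::qbeta(c(a, 1 - a), k + 1, n - k + 1)
}

#' Gametic ratio implied by a recombination fraction and transmission bias
#'
#' Distortion confined to recombinants dilutes into the whole gamete pool:
#' the deviation is `d = 100 * rf * (f - 0.5)` percentage points and the
#' pool-wide ratio is `(50 + d) : (50 - d)`. Because published RF and f are
#' usually rounded, ratios recomputed from printed values can differ in the
#' last digit.
#'
#' @param rf recombination fraction (0..1).
#' @param f transmission frequency of the focal allele among recombinants.
#' @return List with `deviation` (percentage points) and `ratio`
#'   (length-2 numeric summing to 100).
#' @export
gametic_ratio <- function(rf, f) {
  if (rf < 0 || rf > 1) stop("rf must lie in [0, 1]", call. = FALSE)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  d <- 100 * rf * (f - 0.5)
  list(deviation = d, ratio = c(50 + d, 50 - d))
}

#' Test NCO gene-conversion events for GC bias
#'
#' For every marker with one strong (G/C) and one weak (A/T) allele, counts
#' the NCOs that acquired the strong vs the weak allele (the acquired allele
#' is the opposite-haplotype allele at each converted marker) and reports a
#' one-tailed exact binomial P for over-transmission of the strong allele.
#' Markers whose two alleles are both strong or both weak carry no
#' weak/strong contrast and are flagged untestable.
#'
#' @param calls data frame from [classify_molecules()] (NCO and, optionally,
#'   terminal_ambiguous rows carry converted marker ids).
#' @param ms the [molecule_set()] the calls came from (supplies the marker
#'   map and, per orientation, which haplotype's allele is acquired). A list
#'   of molecule sets may be given if calls were pooled across orientations,
#'   keyed by orientation label.
#' @param include_terminal also count `terminal_ambiguous` events as NCOs.
#' @return Data frame: `marker`, `testable`, `n`, `k_strong`, `f`, `p_value`
#'   (one-tailed, strong over weak), `strong_allele`.
#' @export
gc_bias_test <- function(calls, ms, include_terminal = FALSE) {
  ms_list <- if (inherits(ms, "molecule_set")) {
    stats::setNames(list(ms), ms$orientation)
  } else ms
  markers <- ms_list[[1]]$markers
  classes <- c("NCO", if (include_terminal) "terminal_ambiguous")
  nco <- calls[calls$class %in% classes & nzchar(calls$converted), , drop = FALSE]
  acquired <- list()
  for (i in seq_len(nrow(nco))) {
    m_set <- ms_list[[nco$orientation[i]]]
    if (is.null(m_set)) stop("no molecule_set for orientation ",
                             nco$orientation[i], call. = FALSE)
    opp <- setdiff(c("A", "B"), m_set$selected_hap)
    for (mk in strsplit(nco$converted[i], ",", fixed = TRUE)[[1]]) {
      j <- match(mk, markers$id)
      al <- if (opp == "A") markers$allele_a[j] else markers$allele_b[j]
      acquired[[length(acquired) + 1]] <- data.frame(marker = mk, allele = al,
                                                     stringsAsFactors = FALSE)
    }
  }
  acq <- if (length(acquired)) do.call(rbind, acquired) else
    data.frame(marker = character(), allele = character())
  out <- lapply(seq_len(nrow(markers)), function(j) {
    cls <- c(markers$class_a[j], markers$class_b[j])
    testable <- length(unique(cls)) == 2
    strong_allele <- if (testable) {
      c(markers$allele_a[j], markers$allele_b[j])[cls == "strong"]
    } else NA_character_
    hits <- acq$allele[acq$marker == markers$id[j]]
    n <- length(hits)
    if (!testable || n == 0) {
      return(data.frame(marker = markers$id[j], testable = testable, n = n,
                        k_strong = if (testable) sum(hits == strong_allele) else NA,
                        f = NA_real_, p_value = NA_real_,
                        strong_allele = strong_allele, stringsAsFactors = FALSE))
    }
    k <- sum(hits == strong_allele)
    tt <- transmission_test(k, n, tail = "one", marker = markers$id[j],
                            focal_class = "strong")
    data.frame(marker = markers$id[j], testable = TRUE, n = n, k_strong = k,
               f = tt$f, p_value = tt$p_value, strong_allele = strong_allele,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
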