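# Pairwise |D'| linkage disequilibrium from phased X-chromosomal panels,
# X-specific Hardy-Weinberg filtering, operational LD-breakdown calling,
# and overlap counting against DSB-cluster intervals.

#' X-chromosome Hardy-Weinberg filter
#'
#' Markers on the X require a joint test: (i) Hardy-Weinberg equilibrium in
#' female genotypes and (ii) equality of allele frequency between male
#' hemizygotes and females. Both components are chi-square with 1 df and are
#' summed into a 2-df statistic; markers with P below `alpha` are removed.
#' Monomorphic markers have statistic 0 and are retained here (the MAF
#' filter of [dprime_matrix()] handles them).
#'
#' @param panel a [haplotype_panel()] containing female (and typically male)
#'   haplotypes.
#' @param alpha significance level; `alpha = 0` retains every marker.
#' @return List with `retained` (marker ids), `stats` (per-marker data frame
#'   with `chisq`, `p_value`) and `alpha`.
#' @export
x_hwe_filter <- function(panel, alpha = 0.05) {
  sx <- panel$samples
  fem <- sx$sex == "female"
  if (!any(fem)) stop("X-chromosome HWE test undefined without females",
                      call. = FALSE)
  f_samples <- unique(sx$sample[fem])
  male_rows <- which(sx$sex == "male")
  m <- panel$markers
  stats_out <- lapply(seq_len(nrow(m)), function(j) {
    a <- m$ref[j]
    # female genotype counts
    g <- vapply(f_samples, function(s) {
      rows <- which(sx$sample == s)
      sum(panel$alleles[rows, j] == a, na.rm = TRUE)
    }, numeric(1))
    nf <- length(g)
    n_aa <- sum(g == 2); n_ab <- sum(g == 1); n_bb <- sum(g == 0)
    pf <- (2 * n_aa + n_ab) / (2 * nf)
    exp_cnt <- nf * c(pf^2, 2 * pf * (1 - pf), (1 - pf)^2)
    obs <- c(n_aa, n_ab, n_bb)
    chi_hwe <- if (pf %in% c(0, 1)) 0 else
      sum((obs - exp_cnt)^2 / pmax(exp_cnt, .Machine$double.eps))
    # male vs female allele-frequency equality
    if (length(male_rows)) {
      ma <- sum(panel$alleles[male_rows, j] == a, na.rm = TRUE)
      mb <- length(male_rows) - ma
      tab <- matrix(c(ma, mb, 2 * n_aa + n_ab, n_ab + 2 * n_bb), 2, 2)
      chi_freq <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 0 else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    } else chi_freq <- 0
    chisq <- unname(chi_hwe + chi_freq)
    data.frame(id = m$id[j], chisq = chisq,
               p_value = stats::pchisq(chisq, df = 2, lower.tail = FALSE))
  })
  st <- do.call(rbind, stats_out)
  list(retained = st$id[st$p_value >= alpha | alpha == 0], stats = st,
       alpha = alpha)
}

#' Pairwise |D'| matrix from a phased panel
#'
#' For each marker pair, `D = p_AB - p_A * p_B` over complete haplotypes and
#' `D' = D / Dmax`, where `Dmax = min(p_A * p_b, p_a * p_B)` when `D > 0` and
#' `min(p_A * p_B, p_a * p_b)` otherwise; the absolute value is stored.
#' Markers with minor allele frequency at or below `maf_min` (or monomorphic
#' after filtering) are excluded.
#'
#' @param panel a [haplotype_panel()].
#' @param maf_min minor-allele-frequency threshold (markers retained when
#'   MAF > `maf_min`).
#' @param markers optional character vector restricting to pre-filtered
#'   marker ids (e.g. the `retained` set of [x_hwe_filter()]).
#' @return An object of class `ld_matrix`: `ids`, `pos`, `chrom`, `dprime`
#'   (symmetric matrix with unit diagonal), and filter provenance.
#' @export
dprime_matrix <- function(panel, maf_min = 0.2, markers = NULL) {
  m <- panel$markers
  keep <- seq_len(nrow(m))
  if (!is.null(markers)) keep <- keep[m$id %in% markers]
  X <- panel$alleles[, keep, drop = FALSE] == matrix(m$ref[keep],
                                                     nrow(panel$alleles),
                                                     length(keep), byrow = TRUE)
  p <- colMeans(X, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  poly <- maf > maf_min
  dropped <- m$id[keep][!poly]
  keep <- keep[poly]
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  k <- length(keep)
  D <- matrix(NA_real_, k, k, dimnames = list(m$id[keep], m$id[keep]))
  diag(D) <- 1
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      pA <- mean(X[ok, i]); pB <- mean(X[ok, j])
      pAB <- mean(X[ok, i] & X[ok, j])
      Dij <- pAB - pA * pB
      dmax <- if (Dij > 0) min(pA * (1 - pB), (1 - pA) * pB) else
        min(pA * pB, (1 - pA) * (1 - pB))
      D[i, j] <- D[j, i] <- if (dmax == 0) NA_real_ else abs(Dij) / dmax
    }
  }
  structure(list(ids = m$id[keep], pos = m$pos[keep],
                 chrom = attr(panel, "chrom") %||% "chrX", dprime = D,
                 provenance = list(maf_min = maf_min,
                                   hwe_prefiltered = !is.null(markers),
                                   dropped_maf = dropped)),
            class = "ld_matrix")
}

#' EM estimate of two-locus gamete frequencies from unphased genotypes
#'
#' For unphased diploid genotypes (0/1/2 copies of the reference allele at
#' each of two markers) the four gamete frequencies are estimated by EM over
#' the double-heterozygote phase ambiguity. Provided for panels without
#' phasing; the phased haplotype route is the default throughout.
#'
#' @param g1,g2 integer vectors of genotype dosages (0, 1, 2).
#' @param tol convergence tolerance on the AB frequency.
#' @param max_iter iteration cap.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` summing to 1.
#' @export
em_gamete_frequencies <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) stop("no complete genotype pairs", call. = FALSE)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  pAB <- pA * pB
  dh <- g1 == 1 & g2 == 1                    # double heterozygotes
  # fixed gamete contributions from unambiguous genotypes
  # each non-double-het individual contributes 2 phase-resolved gametes
  h1 <- g1[!dh]; h2 <- g2[!dh]
  fixed <- c(
    AB = sum(ifelse(h1 == 2, h2, ifelse(h1 == 1 & h2 == 2, 1, 0))),
    Ab = sum(ifelse(h1 == 2, 2 - h2, ifelse(h1 == 1 & h2 == 0, 1, 0))),
    aB = sum(ifelse(h1 == 0, h2, ifelse(h1 == 1 & h2 == 2, 1, 0))),
    ab = sum(ifelse(h1 == 0, 2 - h2, ifelse(h1 == 1 & h2 == 0, 1, 0))))
  n_dh <- sum(dh)
  for (it in seq_len(max_iter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    cis <- pAB * pab; trans <- pAb * paB
    w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    cnt <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    new_pAB <- cnt[["AB"]] / (2 * n)
    if (abs(new_pAB - pAB) < tol) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
}

#' Call regions of LD breakdown from a |D'| matrix
#'
#' Operationalizes the visual reading of an LD heat map: for each adjacent
#' marker gap, the mean |D'| over all cross pairs spanning the gap within a
#' `window_markers`-marker window each side is computed; gaps whose mean
#' falls below `threshold` are merged into maximal breakdown intervals. The
#' window and threshold are analysis parameters and are recorded in the
#' output so downstream counts carry their provenance.
#'
#' @param ldm an [dprime_matrix()] result.
#' @param window_markers markers considered on each side of a gap.
#' @param threshold mean-|D'| value below which a gap is called broken down.
#' @return An `epar_intervals` data frame of breakdown regions with an
#'   attribute `provenance`; zero rows when no gap falls below threshold.
#' @export
ld_breakdown_regions <- function(ldm, window_markers = 4, threshold = 0.5) {
  k <- length(ldm$ids)
  if (k < 2 * window_markers)
    stop("need at least ", 2 * window_markers, " markers", call. = FALSE)
  gap_mean <- numeric(k - 1)
  for (g in seq_len(k - 1)) {
    li <- max(1, g - window_markers + 1):g
    ri <- (g + 1):min(k, g + window_markers)
    vals <- ldm$dprime[li, ri, drop = FALSE]
    gap_mean[g] <- mean(vals, na.rm = TRUE)
  }
  broken <- !is.na(gap_mean) & gap_mean < threshold
  runs <- rle(broken)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  idx <- which(runs$values)
  out <- if (length(idx)) {
    genomic_intervals(chrom = ldm$chrom,
                      start = ldm$pos[starts[idx]],
                      end = ldm$pos[ends[idx] + 1],
                      label = paste0("ld_breakdown_", seq_along(idx)))
  } else genomic_intervals()
  attr(out, "provenance") <- list(window_markers = window_markers,
                                  threshold = threshold,
                                  gap_mean = gap_mean)
  out
}

#' Count correspondence between LD-breakdown regions and DSB clusters
#'
#' Overlap means >= 1 bp intersection of the half-open intervals.
#'
#' @param ld_regions intervals from [ld_breakdown_regions()].
#' @param dsb_clusters DSB cluster intervals ([read_intervals()]).
#' @return List: `n_ld`, `n_ld_overlapping`, `n_dsb`, `n_dsb_overlapping`,
#'   and a logical `pairs` matrix (LD region x cluster).
#' @export
overlap_counts <- function(ld_regions, dsb_clusters) {
  nl <- nrow(ld_regions); nd <- nrow(dsb_clusters)
  pairs <- matrix(FALSE, nl, nd)
  if (nl && nd) {
    for (i in seq_len(nl)) {
      pairs[i, ] <- ld_regions$chrom[i] == dsb_clusters$chrom &
        ld_regions$start[i] < dsb_clusters$end &
        dsb_clusters$start < ld_regions$end[i]
    }
  }
  list(n_ld = nl, n_ld_overlapping = sum(rowSums(pairs) > 0),
       n_dsb = nd, n_dsb_overlapping = sum(colSums(pairs) > 0),
       pairs = pairs)
}
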