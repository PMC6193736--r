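# Classification of typed sperm molecules into recombinant classes, and
# recombination-fraction estimation with exact Poisson (Garwood) intervals.

#' Classify one typed sperm molecule
#'
#' Converts the allele vector into haplotype indicators and classifies the
#' molecule. In a full assay only recombinant molecules amplify, so a single
#' haplotype switch is a crossover (CO), two or more switches are `complex`,
#' and a switch-free molecule contradicts the selection and is `unscorable`.
#' In a half assay the selected haplotype amplifies regardless: an all-selected
#' molecule is `parental`; an internal run of opposite-haplotype alleles
#' flanked on both sides by selected alleles is a non-crossover (NCO); a
#' switch persisting to the universal-primer end is a CO, unless it involves
#' only the terminal marker adjacent to the universal primer, in which case CO
#' and NCO cannot be distinguished and the call is `terminal_ambiguous`.
#'
#' Missing calls are allowed: a switch is placed in the smallest interval
#' consistent with the non-missing calls, and a molecule whose class is
#' itself ambiguous (or with fewer than two scored markers) is `unscorable`.
#'
#' @param alleles character vector of typed alleles (`NA` = missing), aligned
#'   with the marker map.
#' @param markers a [marker_map()].
#' @param design `"full"` or `"half"`.
#' @param selected_hap for half assays, the amplified haplotype `"A"`/`"B"`.
#' @param universal_end for half assays, `"distal"` or `"proximal"`.
#' @param molecule_id identifier used in the returned call and in errors.
#' @param orientation orientation label carried through to the call.
#' @return A list of class `recombinant_call` with elements `molecule`,
#'   `class`, `bp_left`/`bp_right` (flanking marker ids for CO), `converted`
#'   (marker ids for NCO), and `orientation`.
#' @export
classify_molecule <- function(alleles, markers, design = c("full", "half"),
                              selected_hap = NULL, universal_end = NULL,
                              molecule_id = "mol", orientation = "1") {
  design <- match.arg(design)
  if (length(alleles) != nrow(markers))
    stop("molecule '", molecule_id, "': ", length(alleles),
         " alleles but marker map has ", nrow(markers), call. = FALSE)
  hap <- ifelse(is.na(alleles), NA_character_,
                ifelse(alleles == markers$allele_a, "A",
                       ifelse(alleles == markers$allele_b, "B", "?")))
  if (any(hap == "?", na.rm = TRUE))
    stop("molecule '", molecule_id, "': allele not in marker's pair at ",
         markers$id[which(hap == "?")[1]], call. = FALSE)

  call_out <- function(class, bp = c(NA_character_, NA_character_),
                       converted = character(0)) {
    structure(list(molecule = molecule_id, class = class,
                   bp_left = bp[1], bp_right = bp[2],
                   converted = converted, orientation = orientation),
              class = "recombinant_call")
  }

  scored <- which(!is.na(hap))
  if (length(scored) < 2) return(call_out("unscorable"))
  s_hap <- hap[scored]
  switches <- which(s_hap[-1] != s_hap[-length(s_hap)])

  if (design == "full") {
    if (length(switches) == 0) return(call_out("unscorable"))
    if (length(switches) > 1) return(call_out("complex"))
    i <- switches
    return(call_out("CO", bp = c(markers$id[scored[i]], markers$id[scored[i + 1]])))
  }

  # half assay: orient so the universal primer is to the right of the vector
  if (is.null(selected_hap) || is.null(universal_end))
    stop("half-assay classification requires selected_hap and universal_end",
         call. = FALSE)
  flip <- identical(universal_end, "distal")
  oh <- if (flip) rev(hap) else hap
  midx <- if (flip) rev(seq_len(nrow(markers))) else seq_len(nrow(markers))
  opp <- setdiff(c("A", "B"), selected_hap)

  sc <- which(!is.na(oh))
  v <- oh[sc]
  if (all(v == selected_hap)) return(call_out("parental"))
  # runs of opposite-haplotype alleles among scored markers
  r <- rle(v == opp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  opp_runs <- which(r$values)
  if (v[1] == opp) return(call_out("unscorable"))  # contradicts ASP selection
  if (length(opp_runs) > 1) return(call_out("complex"))
  a <- starts[opp_runs]; b <- ends[opp_runs]
  run_markers <- midx[sc[a:b]]
  last_marker <- midx[length(oh)]
  reaches_end <- (b == length(v))
  if (!reaches_end) {
    # flanked by selected alleles on both sides, but if the markers between
    # the run's end and the next selected call are missing and include the
    # terminal marker the class could still be CO -> that cannot happen here
    # because a scored selected allele lies to the right of the run.
    return(call_out("NCO", converted = markers$id[sort(run_markers)]))
  }
  # run reaches the last *scored* marker; if terminal map marker is unscored,
  # CO vs NCO (switch back in the unscored tail) is ambiguous
  if (sc[b] != length(oh)) return(call_out("unscorable"))
  if (length(run_markers) == 1 && run_markers[1] == last_marker)
    return(call_out("terminal_ambiguous",
                    converted = markers$id[run_markers]))
  left_flank <- midx[sc[a - 1]]
  first_opp <- midx[sc[a]]
  bp <- sort(c(left_flank, first_opp))
  call_out("CO", bp = markers$id[bp])
}

#' Classify every molecule of a molecule set
#'
#' @param ms a [molecule_set()].
#' @return A data frame with one row per molecule: `molecule`, `class`,
#'   `bp_left`, `bp_right`, `converted` (comma-separated marker ids),
#'   `orientation`.
#' @export
classify_molecules <- function(ms) {
  calls <- lapply(seq_len(nrow(ms$alleles)), function(i) {
    classify_molecule(ms$alleles[i, ], ms$markers, design = ms$design,
                      selected_hap = ms$selected_hap,
                      universal_end = ms$universal_end,
                      molecule_id = rownames(ms$alleles)[i],
                      orientation = ms$orientation)
  })
  data.frame(
    molecule = vapply(calls, `[[`, character(1), "molecule"),
    class = vapply(calls, `[[`, character(1), "class"),
    bp_left = vapply(calls, function(x) x$bp_left %||% NA_character_, character(1)),
    bp_right = vapply(calls, function(x) x$bp_right %||% NA_character_, character(1)),
    converted = vapply(calls, function(x) paste(x$converted, collapse = ","),
                       character(1)),
    orientation = vapply(calls, `[[`, character(1), "orientation"),
    stringsAsFactors = FALSE)
}

RECOMBINANT_CLASSES <- c("parental", "CO", "NCO", "terminal_ambiguous",
                         "complex", "unscorable")

#' Tabulate recombinant classes
#'
#' @param calls data frame from [classify_molecules()].
#' @return Named numeric vector over all six classes.
#' @export
class_counts <- function(calls) {
  cnt <- stats::setNames(numeric(length(RECOMBINANT_CLASSES)), RECOMBINANT_CLASSES)
  tab <- table(calls$class)
  cnt[names(tab)] <- as.numeric(tab)
  cnt
}

#' Apportion terminal-ambiguous events between CO and NCO
#'
#' In half assays a haplotype switch involving only the terminal marker next
#' to the universal primer cannot be classified; under the default policy
#' half of such events are designated COs and half NCOs (fractional counts
#' permitted). The `all_CO` / `all_NCO` policies bound the two extremes.
#'
#' @param calls data frame from [classify_molecules()], or a named count
#'   vector as returned by [class_counts()].
#' @param policy `"half_split"`, `"all_CO"` or `"all_NCO"`.
#' @return Named numeric class counts with the `terminal_ambiguous` mass
#'   moved into `CO`/`NCO`.
#' @export
apportion_terminal_events <- function(calls, policy = c("half_split", "all_CO",
                                                        "all_NCO")) {
  policy <- match.arg(policy)
  cnt <- if (is.data.frame(calls)) class_counts(calls) else {
    out <- stats::setNames(numeric(length(RECOMBINANT_CLASSES)),
                           RECOMBINANT_CLASSES)
    out[names(calls)] <- as.numeric(calls)
    out
  }
  t_amb <- cnt[["terminal_ambiguous"]]
  add <- switch(policy,
                half_split = c(CO = t_amb / 2, NCO = t_amb / 2),
                all_CO = c(CO = t_amb, NCO = 0),
                all_NCO = c(CO = 0, NCO = t_amb))
  cnt["CO"] <- cnt["CO"] + add["CO"]
  cnt["NCO"] <- cnt["NCO"] + add["NCO"]
  cnt["terminal_ambiguous"] <- 0
  cnt
}

#' Estimate a recombination fraction with its 95% confidence interval
#'
#' The point estimate is `k/N` recombinants per sperm screened. The default
#' interval is the exact (Garwood) chi-square Poisson interval for the count
#' `k`, divided by `N`; exactness matters at the small counts typical of
#' sperm assays. A normal approximation is available by flag.
#'
#' @param k recombinant count (may be fractional after apportionment).
#' @param N sperm screened.
#' @param level confidence level (default 0.95).
#' @param method `"garwood"` (exact Poisson) or `"normal"`.
#' @return An object of class `rate_estimate`: `k`, `N`, `rf` (fraction),
#'   `rf_pct`, `ci_low_pct`, `ci_high_pct`, `level`, `method`.
#' @export
estimate_rf <- function(k, N, level = 0.95, method = c("garwood", "normal")) {
  method <- match.arg(method)
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (k < 0 || k > N) stop("k must satisfy 0 <= k <= N", call. = FALSE)
  rf <- k / N
  a <- 1 - level
  if (method == "garwood") {
    lo <- if (k == 0) 0 else stats::qchisq(a / 2, 2 * k) / 2
    hi <- stats::qchisq(1 - a / 2, 2 * k + 2) / 2
    ci <- c(lo, hi) / N
  } else {
    z <- stats::qnorm(1 - a / 2)
    ci <- pmax(0, rf + c(-1, 1) * z * sqrt(k) / N)
  }
  structure(list(k = k, N = N, rf = rf, rf_pct = 100 * rf,
                 ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2],
                 level = level, method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("RF = %.*f%% (%d%% CI %.*f-%.*f%%), %g recombinants / %d sperm [%s]\n",
              digits, x$rf_pct, round(100 * x$level), digits, x$ci_low_pct,
              digits, x$ci_high_pct, x$k, x$N, x$method))
  invisible(x)
}

#' Compare two recombination-fraction estimates
#'
#' Fold change (larger over smaller) and a conditional exact binomial test:
#' given `k1 + k2` events, `k1` is binomial with success probability
#' `N1/(N1+N2)` under rate equality. The two-tailed P doubles the smaller
#' tail, capped at 1.
#'
#' @param est1,est2 objects from [estimate_rf()].
#' @return List with `fold` (>= 1, `Inf` if one rate is zero), `p_value`,
#'   and the conditional `n`/`p0` used.
#' @export
compare_rates <- function(est1, est2) {
  if (est1$N <= 0 || est2$N <= 0) stop("both N must be positive", call. = FALSE)
  rfs <- c(est1$rf, est2$rf)
  fold <- if (min(rfs) == 0) {
    if (max(rfs) == 0) 1 else Inf
  } else max(rfs) / min(rfs)
  n <- round(est1$k + est2$k)
  p0 <- est1$N / (est1$N + est2$N)
  k1 <- round(est1$k)
  if (n == 0) {
    p <- 1
  } else {
    lower <- stats::pbinom(k1, n, p0)
    upper <- stats::pbinom(k1 - 1, n, p0, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  }
  list(fold = fold, p_value = p, n = n, p0 = p0,
       test = "conditional exact binomial, two-tailed by tail doubling")
}
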