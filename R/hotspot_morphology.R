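# Recombination-activity profiles along the assayed interval and
# least-squares Gaussian fits to the breakpoint distribution.

#' Per-interval recombination activity
#'
#' Each crossover is localized to an inter-marker interval by its flanking
#' markers. Interval RF = events/N, genetic length = 100*RF cM, and activity
#' = genetic length divided by the physical length in Mb. A crossover whose
#' flanking markers are not adjacent (missing internal calls) contributes to
#' every spanned interval in proportion to physical length, so total genetic
#' length is conserved at `100*k/N` cM.
#'
#' @param co_calls data frame of CO calls with `bp_left`/`bp_right` marker ids
#'   (rows of [classify_molecules()] with class `"CO"` are used; other rows
#'   are ignored), or a count vector named by `"left|right"` interval keys.
#' @param markers a [marker_map()].
#' @param N sperm screened.
#' @return Data frame with one row per inter-marker interval: `left_id`,
#'   `right_id`, `start`, `end`, `length_bp`, `events`, `rf`, `cM`,
#'   `cm_per_mb`.
#' @export
interval_activity <- function(co_calls, markers, N) {
  m <- nrow(markers)
  if (m < 2) stop("need at least two markers", call. = FALSE)
  ev <- numeric(m - 1)  # events per adjacent inter-marker interval
  if (is.data.frame(co_calls)) {
    cos_ <- if ("class" %in% names(co_calls)) {
      co_calls[co_calls$class == "CO", , drop = FALSE]
    } else co_calls
    for (i in seq_len(nrow(cos_))) {
      li <- match(cos_$bp_left[i], markers$id)
      ri <- match(cos_$bp_right[i], markers$id)
      if (is.na(li) || is.na(ri))
        stop("event interval (", cos_$bp_left[i], ", ", cos_$bp_right[i],
             ") not in marker map", call. = FALSE)
      if (li > ri) { tmp <- li; li <- ri; ri <- tmp }
      if (li == ri) stop("degenerate event interval at ", cos_$bp_left[i],
                         call. = FALSE)
      span <- li:(ri - 1)
      w <- diff(markers$pos)[span]
      ev[span] <- ev[span] + w / sum(w)
    }
  } else stop("co_calls must be a data frame of calls", call. = FALSE)
  len <- diff(markers$pos)
  rf <- ev / N
  cm <- 100 * rf
  data.frame(left_id = markers$id[-m], right_id = markers$id[-1],
             start = markers$pos[-m], end = markers$pos[-1],
             length_bp = len, events = ev, rf = rf, cM = cm,
             cm_per_mb = cm / (len / 1e6), stringsAsFactors = FALSE)
}

#' Least-squares Gaussian fit of hotspot morphology
#'
#' Crossovers are only localized to inter-marker intervals, so the fit is to
#' the empirical cumulative breakpoint proportion evaluated at marker
#' positions (each event counted at its interval's right marker), which
#' avoids inventing within-interval positions. The Gaussian CDF
#' `pnorm(x, centre, sigma)` is fitted by deterministic grid search over
#' (centre, sigma) followed by Nelder-Mead refinement (RSS tolerance 1e-8).
#'
#' The hotspot width is reported as the central 95% interval of the fitted
#' Gaussian, `3.92 * sigma`. Peak activity is the total genetic length times
#' the fitted density at the centre, scaled to cM/Mb.
#'
#' @param co_calls CO calls as for [interval_activity()].
#' @param markers a [marker_map()].
#' @param N sperm screened (needed for peak activity; may be `NULL`).
#' @return An object of class `hotspot_fit`: `centre`, `sigma`, `width95`,
#'   `peak_cm_per_mb`, `rss`, `n_events`, `se_centre`, `se_sigma`.
#' @export
fit_normal <- function(co_calls, markers, N = NULL) {
  act <- interval_activity(co_calls, markers,
                           N = if (is.null(N)) 1 else N)
  ev <- act$events
  total <- sum(ev)
  if (total <= 0) stop("no crossover events to fit", call. = FALSE)
  if (sum(ev > 0) < 1) stop("no informative intervals", call. = FALSE)
  if (sum(ev > 1e-9) == 1)
    stop("all events fall in a single inter-marker interval; sigma is ",
         "unidentifiable - report the exact interval instead", call. = FALSE)
  if (nrow(act) < 3)
    stop("need at least three inter-marker intervals", call. = FALSE)
  # empirical CDF at marker positions (events counted at right marker)
  x <- markers$pos
  Femp <- c(0, cumsum(ev) / total)   # at markers 1..m
  rss_fun <- function(par) {
    if (par[2] <= 0) return(Inf)
    sum((stats::pnorm(x, par[1], par[2]) - Femp)^2)
  }
  span <- diff(range(x))
  mus <- seq(min(x), max(x), length.out = 101)
  sigmas <- exp(seq(log(max(span / 200, 1)), log(span), length.out = 41))
  grid_rss <- outer(seq_along(mus), seq_along(sigmas),
                    Vectorize(function(i, j) rss_fun(c(mus[i], sigmas[j]))))
  best <- arrayInd(which.min(grid_rss), dim(grid_rss))
  opt <- stats::optim(c(mus[best[1]], sigmas[best[2]]), rss_fun,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  centre <- opt$par[1]; sigma <- abs(opt$par[2]); rss <- opt$value
  # asymptotic SEs from the numerical Jacobian of the fitted CDF
  eps <- c(max(1e-4 * span, 1e-3), max(1e-4 * sigma, 1e-3))
  J <- cbind(
    (stats::pnorm(x, centre + eps[1], sigma) -
       stats::pnorm(x, centre - eps[1], sigma)) / (2 * eps[1]),
    (stats::pnorm(x, centre, sigma + eps[2]) -
       stats::pnorm(x, centre, sigma - eps[2])) / (2 * eps[2]))
  dof <- max(length(x) - 2, 1)
  s2 <- rss / dof
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA, 2, 2))
  peak <- if (is.null(N)) NA_real_ else {
    total_cm <- 100 * total / N
    total_cm * stats::dnorm(0, 0, sigma) * 1e6
  }
  structure(list(centre = centre, sigma = sigma, width95 = 3.92 * sigma,
                 peak_cm_per_mb = peak, rss = rss, n_events = total,
                 se_centre = sqrt(covm[1, 1]), se_sigma = sqrt(covm[2, 2])),
            class = "hotspot_fit")
}

#' @export
print.hotspot_fit <- function(x, ...) {
  cat(sprintf("hotspot_fit: centre %.0f bp, sigma %.0f bp, 95%% width %.0f bp",
              x$centre, x$sigma, x$width95))
  if (!is.na(x$peak_cm_per_mb))
    cat(sprintf(", peak %.0f cM/Mb", x$peak_cm_per_mb))
  cat(sprintf(" (%.3g events, RSS %.3g)\n", x$n_events, x$rss))
  invisible(x)
}

#' Centre-point displacement between reciprocal orientations
#'
#' Transmission distortion shifts the crossover breakpoint distributions of
#' the two reciprocal orientations in opposite directions; the signed
#' difference of the fitted centres measures this crossover asymmetry.
#'
#' @param fit1,fit2 `hotspot_fit` objects for the two orientations over the
#'   same marker map.
#' @return List with `offset_bp` (= centre1 - centre2) and `se_bp` (combined
#'   standard error from the two fit covariances).
#' @export
asymmetry_offset <- function(fit1, fit2) {
  if (!inherits(fit1, "hotspot_fit") || !inherits(fit2, "hotspot_fit"))
    stop("both arguments must be successful hotspot fits", call. = FALSE)
  list(offset_bp = fit1$centre - fit2$centre,
       se_bp = sqrt(fit1$se_centre^2 + fit2$se_centre^2))
}
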