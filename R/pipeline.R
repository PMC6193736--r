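# Orchestration: a validated config drives the analysis stages in
# dependency order, every output is written as JSON, and a manifest records
# the config snapshot, input checksums and per-stage decisions.

pipeline_schema <- list(
  rates = c("counts"),                       # list of {label, k, n}
  sperm_sim = c("rf", "centre", "sigma", "n_sperm"),
  minrate = c("events", "generations", "lineages"),
  tmrca = c("str_table", "mu_table", "years"),
  ld = c("vcf", "sex_table", "maf", "alpha", "dsb_bed")
)

validate_config <- function(config) {
  if (is.null(config$seed)) config$seed <- 1L
  bad <- setdiff(names(config), c("seed", "out_dir", names(pipeline_schema)))
  if (length(bad))
    stop("config schema violation; unknown key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(config$tmrca) && is.null(config$tmrca$years) &&
      (is.null(config$tmrca$str_table) || is.null(config$tmrca$mu_table)))
    stop("config schema violation; tmrca needs 'years' or ",
         "'str_table' + 'mu_table'", call. = FALSE)
  for (key in c("str_table", "mu_table")) {
    p <- config$tmrca[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config schema violation; tmrca$", key, ": no such file '", p, "'",
           call. = FALSE)
  }
  if (!is.null(config$ld)) {
    for (key in c("vcf", "sex_table"))
      if (is.null(config$ld[[key]]))
        stop("config schema violation; ld$", key, " is required", call. = FALSE)
    for (key in c("vcf", "sex_table")) {
      p <- config$ld[[key]]
      if (!file.exists(p))
        stop("config schema violation; ld$", key, ": no such file '", p, "'",
             call. = FALSE)
    }
  }
  config
}

#' Run the analysis pipeline from a configuration
#'
#' The configuration (a list, or a path to a YAML/JSON file) may contain any
#' of the sections `rates` (recombination fractions from counts), `sperm_sim`
#' (simulate molecules, classify, estimate and fit morphology), `minrate`
#' (minimum rate and cM/Mb conversion), `tmrca` (ASD dating from STR tables,
#' or a years-to-generations conversion) and `ld` (|D'| landscape from a
#' phased VCF with breakdown calling and DSB overlap counts). Unknown keys
#' are schema errors. All stochastic stages are seeded from `config$seed`.
#'
#' @param config list or path to a YAML/JSON config file.
#' @param out_dir output directory for the JSON stage outputs and manifest;
#'   `NULL` returns results without writing.
#' @param dry_run validate the config and return the normalized form
#'   without touching inputs or writing outputs.
#' @return List of stage results plus `manifest`, invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- validate_config(config)
  if (dry_run) return(list(config = config, valid = TRUE))
  seed <- as.integer(config$seed %||% 1L)
  results <- list()
  decisions <- list(ci_method = "garwood", credible_prior = "Beta(1,1)",
                    two_tailed = "tail doubling, capped at 1")

  if (!is.null(config$rates)) {
    ests <- lapply(config$rates$counts, function(ct) {
      n_ct <- ct$N %||% ct$n
      e <- estimate_rf(ct$k, n_ct)
      list(label = ct$label %||% paste0(ct$k, "/", n_ct), k = e$k, N = e$N,
           rf_pct = e$rf_pct, ci_low_pct = e$ci_low_pct,
           ci_high_pct = e$ci_high_pct)
    })
    cmp <- if (length(config$rates$counts) >= 2) {
      c1 <- config$rates$counts[[1]]; c2 <- config$rates$counts[[2]]
      compare_rates(estimate_rf(c1$k, c1$N %||% c1$n),
                    estimate_rf(c2$k, c2$N %||% c2$n))[
        c("fold", "p_value")]
    } else NULL
    results$rates <- list(estimates = ests, comparison = cmp)
  }

  if (!is.null(config$sperm_sim)) {
    p <- config$sperm_sim
    mk <- if (!is.null(p$markers)) read_marker_map(p$markers) else {
      pos <- seq(0, 5000, length.out = 12)
      marker_map(paste0("s", 1:12), round(pos), rep(c("A", "C"), 6),
                 rep(c("G", "T"), 6))
    }
    sim <- simulate_sperm_molecules(
      mk, design = p$design %||% "full", rf = p$rf, centre = p$centre,
      sigma = p$sigma, f_bias = p$f_bias %||% 0.5,
      nco_fraction = p$nco_fraction %||% 0, n_sperm = p$n_sperm, seed = seed)
    calls <- do.call(rbind, lapply(sim$molecules, classify_molecules))
    counts <- apportion_terminal_events(calls)
    est <- estimate_rf(counts[["CO"]] + counts[["NCO"]], p$n_sperm)
    fit <- tryCatch(fit_normal(calls, mk, N = p$n_sperm),
                    error = function(e) NULL)
    results$sperm_sim <- list(
      class_counts = as.list(counts),
      rf = list(rf_pct = est$rf_pct, ci_low_pct = est$ci_low_pct,
                ci_high_pct = est$ci_high_pct),
      fit = if (!is.null(fit)) fit[c("centre", "sigma", "width95",
                                     "peak_cm_per_mb")],
      truth = sim$truth$params[c("rf", "centre", "sigma")])
  }

  if (!is.null(config$minrate)) {
    p <- config$minrate
    mr <- min_rate(p$events, p$generations, p$lineages)
    results$minrate <- list(events = mr$events, generations = mr$generations,
                            lineages = mr$lineages, rate = mr$rate,
                            pct = mr$pct)
    if (!is.null(p$region_length))
      results$minrate$cm_per_mb <- rate_to_cm_per_mb(mr$rate, p$region_length)
  }

  if (!is.null(config$tmrca)) {
    p <- config$tmrca
    results$tmrca <- if (!is.null(p$str_table)) {
      strs <- read_str_table(p$str_table, p$mu_table)
      est <- asd_tmrca(strs, generation_time = p$generation_time %||% 31)
      list(t_generations = est$t_generations, t_years = est$t_years,
           se_years = est$se_years, generation_time = est$generation_time)
    } else {
      gt <- p$generation_time %||% 31
      list(t_years = p$years, generation_time = gt,
           t_generations = generations_from_years(p$years, gt))
    }
  }

  if (!is.null(config$ld)) {
    p <- config$ld
    sex <- utils::read.delim(p$sex_table, stringsAsFactors = FALSE)
    panel <- read_phased_panel(p$vcf, sex)
    hwe <- x_hwe_filter(panel, alpha = p$alpha %||% 0.05)
    ldm <- dprime_matrix(panel, maf_min = p$maf %||% 0.2,
                         markers = hwe$retained)
    br <- ld_breakdown_regions(ldm,
                               window_markers = p$window_markers %||% 4,
                               threshold = p$threshold %||% 0.5)
    results$ld <- list(n_markers = length(ldm$ids),
                       n_dropped_hwe = nrow(panel$markers) -
                         length(hwe$retained),
                       breakdown = as.data.frame(br))
    if (!is.null(p$dsb_bed)) {
      dsb <- read_intervals(p$dsb_bed)
      oc <- overlap_counts(br, dsb)
      results$ld$overlap <- oc[c("n_ld", "n_ld_overlapping", "n_dsb",
                                 "n_dsb_overlapping")]
    }
  }

  input_paths <- unlist(lapply(config[names(config) %in% names(pipeline_schema)],
                               function(s) Filter(function(v)
                                 is.character(v) && length(v) == 1 &&
                                   file.exists(v), s)))
  manifest <- list(
    config = config,
    tool = paste0("eparscan ", as.character(utils::packageVersion("eparscan"))),
    seed = seed,
    decisions = decisions,
    input_checksums = if (length(input_paths))
      as.list(tools::md5sum(unname(unlist(input_paths)))) else list(),
    stages_run = names(results))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (nm in names(results)) {
      pth <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(results[[nm]], pth, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      paths[nm] <- pth
    }
    manifest$output_paths <- as.list(paths)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}
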