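# Shared fixture builders and independent oracles.

# 6-marker map spanning ~3 kb with a mix of strong/weak contrasts
fix_map <- function() {
  marker_map(id = paste0("snp", 1:6),
             pos = c(0L, 500L, 1100L, 1700L, 2300L, 3000L),
             allele_a = c("A", "C", "A", "G", "T", "C"),
             allele_b = c("G", "T", "C", "A", "C", "G"))
}

# turn haplotype letters ("A"/"B", NA allowed) into an allele vector
hap_alleles <- function(map, haps) {
  ifelse(is.na(haps), NA_character_,
         ifelse(haps == "A", map$allele_a, map$allele_b))
}

# build a molecule_set from a list of haplotype-letter vectors
fix_molecules <- function(map, hap_list, design = "full", orientation = "1",
                          selected_hap = NULL, universal_end = NULL,
                          n_sperm = 1000) {
  alleles <- do.call(rbind, lapply(hap_list, hap_alleles, map = map))
  rownames(alleles) <- paste0("mol", seq_along(hap_list))
  molecule_set(map, alleles, design = design, orientation = orientation,
               selected_hap = selected_hap, universal_end = universal_end,
               n_sperm = n_sperm)
}

# independent oracle: two-tailed binomial P by direct probability summation
oracle_two_tailed <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# independent oracle: Beta posterior quantile by density integration + root find
oracle_beta_quantile <- function(p, shape1, shape2) {
  cdf <- function(x) stats::integrate(function(u) stats::dbeta(u, shape1, shape2),
                                      0, x, rel.tol = 1e-10)$value
  stats::uniroot(function(x) cdf(x) - p, c(1e-12, 1 - 1e-12),
                 tol = 1e-10)$root
}

# quadratic-scan overlap oracle
oracle_overlap <- function(a, b) {
  n_a <- 0
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) hit <- TRUE
    }
    n_a <- n_a + hit
  }
  n_b <- 0
  for (j in seq_len(nrow(b))) {
    hit <- FALSE
    for (i in seq_len(nrow(a))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) hit <- TRUE
    }
    n_b <- n_b + hit
  }
  c(n_a, n_b)
}

# panel built directly from explicit haplotype strings (one char per marker)
fix_panel <- function(hap_strings, pos = NULL, n_males = 0,
                      ref = NULL, alt = NULL) {
  n <- length(hap_strings)
  m <- nchar(hap_strings[1])
  alleles <- do.call(rbind, strsplit(hap_strings, ""))
  if (is.null(pos)) pos <- (seq_len(m) - 1L) * 100L
  if (is.null(ref)) ref <- apply(alleles, 2, function(col) col[1])
  if (is.null(alt)) alt <- apply(alleles, 2, function(col) {
    other <- setdiff(unique(col), col[1])
    if (length(other)) other[1] else setdiff(c("A", "C", "G", "T"), col[1])[1]
  })
  markers <- data.frame(id = paste0("m", seq_len(m)), pos = pos,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  n_fem <- (n - n_males) / 2
  samples <- rbind(
    if (n_males) data.frame(sample = paste0("M", seq_len(n_males)),
                            sex = "male", hap_index = 1L),
    if (n_fem) data.frame(sample = rep(paste0("F", seq_len(n_fem)), each = 2),
                          sex = "female", hap_index = rep(1:2, n_fem)))
  haplotype_panel(markers, samples, alleles, "TEST")
}
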