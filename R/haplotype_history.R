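# Block-based haplotype algebra for the X-derived region carried on the Y:
# DSB-cluster-excluding block partition, consensus designation,
# single-crossover reconstruction, panel matching and minimum-event counts.

#' Partition markers into blocks that exclude DSB clusters
#'
#' Markers falling inside any DSB cluster are dropped; the maximal runs of
#' retained markers between consecutive clusters form blocks, indexed from
#' the distal (lowest-coordinate, telomere-proximal) end.
#'
#' @param markers data frame with columns `id` and `pos` (0-based),
#'   positions increasing.
#' @param dsb_clusters intervals ([genomic_intervals()]), 0-based half-open.
#' @return An object of class `block_partition`: `blocks` data frame
#'   (`index`, `start`, `end`, `n_markers`), `marker_ids` list per block,
#'   and `markers` (the retained marker data frame with a `block` column).
#' @export
define_blocks <- function(markers, dsb_clusters) {
  markers <- as.data.frame(markers)
  pos <- markers$pos
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(dsb_clusters))) {
    inside <- inside | (pos >= dsb_clusters$start[i] & pos < dsb_clusters$end[i])
  }
  kept <- markers[!inside, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("no markers retained outside the DSB clusters", call. = FALSE)
  # block id = number of clusters wholly distal of the marker
  starts <- sort(dsb_clusters$start)
  bin <- findInterval(kept$pos, starts)
  block_idx <- cumsum(c(TRUE, diff(bin) != 0))
  kept$block <- block_idx
  blocks <- do.call(rbind, lapply(split(kept, kept$block), function(b) {
    data.frame(index = b$block[1], start = min(b$pos), end = max(b$pos) + 1L,
               n_markers = nrow(b))
  }))
  rownames(blocks) <- NULL
  structure(list(blocks = blocks,
                 marker_ids = split(kept$id, kept$block),
                 markers = kept),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block_partition:", nrow(x$blocks), "blocks,",
      nrow(x$markers), "markers; sizes",
      paste(x$blocks$end - x$blocks$start, collapse = ", "), "bp\n")
  invisible(x)
}

#' Build compound haplotypes over a block partition
#'
#' Collapses each haplotype's alleles within each block into one string, the
#' unit of identity for consensus designation and crossover reconstruction.
#'
#' @param panel a [haplotype_panel()] or a character allele matrix whose
#'   columns are named by marker id.
#' @param partition a [define_blocks()] result.
#' @param sample_ids optional ids per row; defaults to panel sample labels.
#' @param lineage optional lineage tags (e.g. Y sub-haplogroup), recycled.
#' @return Object of class `compound_haplotype_set`: `strings` (character
#'   matrix, haplotypes x blocks), `samples`, `lineage`, `partition`.
#' @export
compound_haplotypes <- function(panel, partition, sample_ids = NULL,
                                lineage = NA_character_) {
  alleles <- if (inherits(panel, "haplotype_panel")) panel$alleles else as.matrix(panel)
  if (is.null(sample_ids)) {
    sample_ids <- if (inherits(panel, "haplotype_panel")) {
      paste0(panel$samples$sample, "_h", panel$samples$hap_index)
    } else rownames(alleles) %||% paste0("hap", seq_len(nrow(alleles)))
  }
  k <- nrow(partition$blocks)
  strings <- matrix(NA_character_, nrow(alleles), k,
                    dimnames = list(sample_ids, paste0("block", seq_len(k))))
  for (b in seq_len(k)) {
    ids <- partition$marker_ids[[b]]
    miss <- setdiff(ids, colnames(alleles))
    if (length(miss))
      stop("marker(s) missing from haplotypes: ", paste(miss, collapse = ", "),
           call. = FALSE)
    strings[, b] <- apply(alleles[, ids, drop = FALSE], 1, paste, collapse = "")
  }
  structure(list(strings = strings, samples = sample_ids,
                 lineage = rep_len(lineage, nrow(alleles)),
                 partition = partition),
            class = "compound_haplotype_set")
}

full_strings <- function(chs) apply(chs$strings, 1, paste, collapse = "|")

#' Designate the consensus compound haplotype
#'
#' The modal full compound haplotype. Ties are reported explicitly as an
#' ambiguity rather than silently broken; if every haplotype is unique an
#' error instructs manual designation.
#'
#' @param chs a [compound_haplotypes()] set.
#' @return List: `consensus` (character vector of block strings),
#'   `multiplicity`, `carriers` (sample ids), `ambiguous` (logical) and, on
#'   a tie, `candidates`.
#' @export
consensus_haplotype <- function(chs) {
  if (nrow(chs$strings) < 2) stop("need at least two haplotypes", call. = FALSE)
  fs <- full_strings(chs)
  tab <- sort(table(fs), decreasing = TRUE)
  if (max(tab) == 1)
    stop("all compound haplotypes are unique; designate a consensus manually",
         call. = FALSE)
  top <- names(tab)[tab == max(tab)]
  ambiguous <- length(top) > 1
  cons_row <- which(fs == top[1])[1]
  list(consensus = chs$strings[cons_row, ],
       multiplicity = as.integer(max(tab)),
       carriers = chs$samples[fs == top[1]],
       ambiguous = ambiguous,
       candidates = if (ambiguous) top else NULL)
}

#' Explain a compound haplotype as one crossover with an incoming X
#'
#' Under the distal-replacement model the Y retains its proximal side at any
#' crossover, so incoming X material lies distal of the breakpoint. The
#' breakpoint is the block boundary immediately proximal of the most
#' proximal block that differs from the consensus; every block distal of it
#' (including consensus-matching ones, which are attributed to coincidental
#' identity) constitutes the inferred incoming haplotype.
#'
#' @param hap character vector of block strings for one haplotype.
#' @param consensus consensus block strings of equal length.
#' @return Object of class `crossover_explanation`: `event` (logical),
#'   `breakpoint_after_block`, `incoming` (block strings 1..breakpoint),
#'   `blocks_differing`, `snp_differences` (per differing block).
#' @export
single_crossover_explanation <- function(hap, consensus) {
  if (length(hap) != length(consensus))
    stop("haplotype and consensus must span the same blocks", call. = FALSE)
  diff_blocks <- which(hap != consensus)
  if (length(diff_blocks) == 0) {
    return(structure(list(event = FALSE, breakpoint_after_block = NA_integer_,
                          incoming = NULL, blocks_differing = integer(0),
                          snp_differences = integer(0)),
                     class = "crossover_explanation"))
  }
  b <- max(diff_blocks)
  snp_diff <- vapply(diff_blocks, function(i) {
    sum(strsplit(hap[i], "")[[1]] != strsplit(consensus[i], "")[[1]])
  }, integer(1))
  structure(list(event = TRUE, breakpoint_after_block = b,
                 incoming = hap[seq_len(b)],
                 blocks_differing = diff_blocks,
                 snp_differences = stats::setNames(snp_diff, diff_blocks)),
            class = "crossover_explanation")
}

#' Match a haplotype against a panel, whole or block by block
#'
#' @param query block strings (character vector) to search for.
#' @param panel_chs a [compound_haplotypes()] set built on the same
#'   partition.
#' @param scope `"full"` (exact full-compound match) or `"per_block"`.
#' @return For `"full"`: list with `matches` (sample ids) and `n`. For
#'   `"per_block"`: data frame `block`, `n_matches`, plus a list column-free
#'   `matches` attribute mapping block index to sample ids.
#' @export
match_haplotypes <- function(query, panel_chs, scope = c("full", "per_block")) {
  scope <- match.arg(scope)
  if (length(query) != ncol(panel_chs$strings))
    stop("query and panel span different block sets", call. = FALSE)
  if (scope == "full") {
    hit <- full_strings(panel_chs) == paste(query, collapse = "|")
    return(list(matches = panel_chs$samples[hit], n = sum(hit)))
  }
  per <- lapply(seq_along(query), function(b) panel_chs$samples[
    panel_chs$strings[, b] == query[b]])
  out <- data.frame(block = seq_along(query),
                    n_matches = vapply(per, length, integer(1)))
  attr(out, "matches") <- per
  out
}

#' Minimum number of recombination events behind a haplotype set
#'
#' Each distinct compound haplotype beyond the first requires at least one
#' recombination (or mutation) event, so the count of distinct compound
#' haplotypes minus one is a lower bound on the events that occurred.
#'
#' @param chs a [compound_haplotypes()] set.
#' @return Integer lower bound.
#' @export
min_recombination_events <- function(chs) {
  if (nrow(chs$strings) < 1) stop("need at least one haplotype", call. = FALSE)
  length(unique(full_strings(chs))) - 1L
}
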