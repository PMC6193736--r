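#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# BED is consumed natively; VCF POS is converted on read (POS - 1) and back
# on write (start + 1).

#' Convert VCF (1-based) positions to internal 0-based coordinates
#'
#' @param pos integer vector of 1-based positions.
#' @return 0-based positions.
#' @export
vcf_to_internal <- function(pos) as.integer(pos) - 1L

#' Convert internal 0-based positions to VCF (1-based) positions
#'
#' @param pos integer vector of 0-based positions.
#' @return 1-based positions.
#' @export
internal_to_vcf <- function(pos) as.integer(pos) + 1L

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open, the BED convention. Used for DSB
#' (double-strand break) clusters, assay windows and LD-breakdown regions.
#'
#' @param chrom chromosome labels.
#' @param start 0-based start positions.
#' @param end end positions (exclusive).
#' @param label free-text labels (e.g. DSB cluster id or PRDM9 allele tag).
#' @return A data frame of class `epar_intervals`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), label = NA_character_) {
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end),
                  label = rep_len(as.character(label), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("epar_intervals", "data.frame")
  x
}

validate_intervals <- function(x, where = "intervals") {
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop(where, ": negative start position", call. = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(where, ": start >= end at row ", bad[1], call. = FALSE)
  invisible(x)
}

#' Read genomic intervals from a BED file
#'
#' Coordinates are kept 0-based half-open as in the file. Lines starting
#' with `track`, `browser` or `#` are skipped.
#'
#' @param path path to a BED file with at least 3 columns.
#' @return An `epar_intervals` data frame in file order.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed BED line ", i, ": fewer than 3 columns", call. = FALSE)
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end))
      stop("malformed BED line ", i, ": non-integer coordinates", call. = FALSE)
    if (start < 0 || start >= end)
      stop("malformed BED line ", i, ": requires 0 <= start < end", call. = FALSE)
    j <- j + 1L
    out[[j]] <- data.frame(chrom = fields[1], start = start, end = end,
                           label = if (length(fields) >= 4) fields[4] else NA_character_,
                           stringsAsFactors = FALSE)
  }
  x <- if (j == 0) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, out[seq_len(j)])
  class(x) <- c("epar_intervals", "data.frame")
  x
}

#' Write genomic intervals to a BED file
#'
#' @param x an `epar_intervals` data frame (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  lab <- ifelse(is.na(x$label), ".", x$label)
  lines <- paste(x$chrom, x$start, x$end, lab, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a marker map
#'
#' An ordered map of heterozygous SNPs for one sperm donor, with the phase
#' assignment of each allele to parental haplotype A or B.
#'
#' @param id marker identifiers.
#' @param pos positions in bp (0-based), strictly increasing.
#' @param allele_a single-base allele carried on haplotype A.
#' @param allele_b single-base allele carried on haplotype B.
#' @return A data frame of class `marker_map` with a `class_a`/`class_b`
#'   column giving the strong (G/C) or weak (A/T) status of each allele.
#' @export
marker_map <- function(id, pos, allele_a, allele_b) {
  x <- data.frame(id = as.character(id), pos = as.integer(pos),
                  allele_a = toupper(as.character(allele_a)),
                  allele_b = toupper(as.character(allele_b)),
                  stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("marker map is empty", call. = FALSE)
  if (any(duplicated(x$id))) stop("duplicated marker ids", call. = FALSE)
  if (any(diff(x$pos) <= 0))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (!all(c(x$allele_a, x$allele_b) %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  if (any(x$allele_a == x$allele_b))
    stop("markers must be heterozygous (two distinct alleles)", call. = FALSE)
  x$class_a <- allele_class(x$allele_a)
  x$class_b <- allele_class(x$allele_b)
  class(x) <- c("marker_map", "data.frame")
  x
}

#' Strong/weak class of a base
#'
#' Strong bases (G, C) pair with three hydrogen bonds; weak bases (A, T)
#' with two. GC-biased gene conversion over-transmits strong alleles.
#'
#' @param allele character vector of single bases.
#' @return "strong" or "weak" per element.
#' @export
allele_class <- function(allele) {
  ifelse(toupper(allele) %in% c("G", "C"), "strong", "weak")
}

#' Read a marker map from TSV
#'
#' Expects columns `id`, `pos`, `allele_a`, `allele_b`.
#'
#' @param path path to a tab-separated file.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(tab)))
    stop("marker map TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  marker_map(tab$id, tab$pos, tab$allele_a, tab$allele_b)
}

#' Write a marker map to TSV
#'
#' @param map a `marker_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("id", "pos", "allele_a", "allele_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a set of typed sperm molecules
#'
#' The unit of recombinant detection: one allele vector per molecule over a
#' marker map, together with the assay design metadata needed to interpret
#' it. Two designs are supported: `full` (reciprocal allele-specific primers
#' at both ends; only recombinant molecules amplify) and `half`
#' (allele-specific primers on one haplotype plus universal primers; both
#' crossovers and non-crossovers are detectable, but switches confined to
#' the terminal marker next to the universal primer are class-ambiguous).
#'
#' @param markers a `marker_map`.
#' @param alleles character matrix, molecules x markers; `NA` = missing call.
#' @param design `"full"` or `"half"`.
#' @param orientation free label for the reciprocal orientation (e.g. `"Ab"`).
#' @param selected_hap for half assays, `"A"` or `"B"`: the haplotype the
#'   allele-specific primers amplify.
#' @param universal_end for half assays, `"distal"` (universal primer beyond
#'   the first marker) or `"proximal"` (beyond the last marker).
#' @param n_sperm total sperm screened (>= number of molecules typed).
#' @param pools optional data frame (`pool`, per-molecule pool id) or a
#'   vector of pool ids, one per molecule.
#' @return An object of class `molecule_set`.
#' @export
molecule_set <- function(markers, alleles, design = c("full", "half"),
                         orientation = "1", selected_hap = NULL,
                         universal_end = NULL, n_sperm, pools = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(markers, "marker_map"))
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != nrow(markers))
    stop("allele matrix has ", ncol(alleles), " columns but marker map has ",
         nrow(markers), " markers", call. = FALSE)
  if (is.null(rownames(alleles)) && nrow(alleles) > 0)
    rownames(alleles) <- paste0("mol", seq_len(nrow(alleles)))
  if (nrow(alleles) > 0) colnames(alleles) <- markers$id
  if (design == "half") {
    if (is.null(selected_hap) || !selected_hap %in% c("A", "B"))
      stop("half assays require selected_hap 'A' or 'B'", call. = FALSE)
    if (is.null(universal_end) || !universal_end %in% c("distal", "proximal"))
      stop("half assays require universal_end 'distal' or 'proximal'",
           call. = FALSE)
  }
  if (n_sperm < nrow(alleles))
    stop("total sperm screened (", n_sperm, ") < molecules typed (",
         nrow(alleles), ")", call. = FALSE)
  for (j in seq_len(ncol(alleles))) {
    ok <- is.na(alleles[, j]) |
      alleles[, j] %in% c(markers$allele_a[j], markers$allele_b[j])
    if (!all(ok))
      stop("molecule '", rownames(alleles)[which(!ok)[1]], "': allele '",
           alleles[which(!ok)[1], j], "' not in pair for marker ",
           markers$id[j], call. = FALSE)
  }
  if (!is.null(pools) && length(pools) != nrow(alleles) && !is.data.frame(pools))
    stop("pools must give one pool id per molecule", call. = FALSE)
  structure(list(markers = markers, alleles = alleles, design = design,
                 orientation = as.character(orientation),
                 selected_hap = selected_hap, universal_end = universal_end,
                 n_sperm = as.integer(n_sperm),
                 pools = if (is.null(pools)) NULL else as.character(unlist(pools))),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("molecule_set:", nrow(x$alleles), "molecules x", nrow(x$markers),
      "markers;", x$design, "assay, orientation", x$orientation, "\n")
  cat("  sperm screened:", x$n_sperm, "\n")
  if (x$design == "half")
    cat("  selected haplotype:", x$selected_hap, "| universal primer end:",
        x$universal_end, "\n")
  invisible(x)
}

#' Read a molecule table from TSV
#'
#' The format is a metadata block of `#key<TAB>value` lines followed by a
#' header row (`molecule`, optional `pool`, then marker ids) and one row per
#' molecule; `.` denotes a missing call.
#'
#' @param path path to the TSV file.
#' @param markers optional `marker_map`; if omitted a map must be
#'   reconstructable from metadata lines `#marker_pos`, `#allele_a`,
#'   `#allele_b` (comma-separated, aligned with the header marker ids).
#' @return A `molecule_set`.
#' @export
read_molecule_table <- function(path, markers = NULL) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- strsplit(sub("^#", "", l), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else NA_character_
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) stop("molecule table has no header row", call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  has_pool <- length(header) >= 2 && header[2] == "pool"
  marker_ids <- header[-seq_len(1 + has_pool)]
  if (is.null(markers)) {
    need <- c("marker_pos", "allele_a", "allele_b")
    if (!all(need %in% names(meta)))
      stop("no marker_map given and metadata lacks ",
           paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
    split1 <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
    markers <- marker_map(marker_ids, as.integer(split1(meta$marker_pos)),
                          split1(meta$allele_a), split1(meta$allele_b))
  }
  if (!identical(marker_ids, markers$id))
    stop("header marker ids do not match marker map", call. = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  n <- length(rows)
  alleles <- matrix(NA_character_, n, length(marker_ids))
  ids <- character(n)
  pools <- if (has_pool) character(n) else NULL
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (length(r) != length(header))
      stop("molecule row ", i, " has ", length(r), " fields, expected ",
           length(header), call. = FALSE)
    ids[i] <- r[1]
    if (has_pool) pools[i] <- r[2]
    a <- r[-seq_len(1 + has_pool)]
    a[a == "."] <- NA_character_
    alleles[i, ] <- a
  }
  rownames(alleles) <- ids
  molecule_set(markers, alleles,
               design = meta$design %||% "full",
               orientation = meta$orientation %||% "1",
               selected_hap = meta$selected_hap,
               universal_end = meta$universal_end,
               n_sperm = as.integer(meta$n_sperm %||% n),
               pools = pools)
}

#' Write a molecule table to TSV
#'
#' Inverse of [read_molecule_table()]; embeds the marker map in the
#' metadata block so the file is self-contained.
#'
#' @param ms a `molecule_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(ms, path) {
  meta <- c(
    paste0("#design\t", ms$design),
    paste0("#orientation\t", ms$orientation),
    if (!is.null(ms$selected_hap)) paste0("#selected_hap\t", ms$selected_hap),
    if (!is.null(ms$universal_end)) paste0("#universal_end\t", ms$universal_end),
    paste0("#n_sperm\t", ms$n_sperm),
    paste0("#marker_pos\t", paste(ms$markers$pos, collapse = ",")),
    paste0("#allele_a\t", paste(ms$markers$allele_a, collapse = ",")),
    paste0("#allele_b\t", paste(ms$markers$allele_b, collapse = ",")))
  has_pool <- !is.null(ms$pools)
  header <- paste(c("molecule", if (has_pool) "pool", ms$markers$id),
                  collapse = "\t")
  a <- ms$alleles
  a[is.na(a)] <- "."
  rows <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(rownames(a)[i], if (has_pool) ms$pools[i], a[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Construct a phased haplotype panel
#'
#' @param markers data frame with columns `id`, `pos` (0-based), `ref`, `alt`.
#' @param samples data frame with columns `sample`, `sex` ("male"/"female"),
#'   `hap_index` (1 for males; 1 and 2 for females), one row per haplotype.
#' @param alleles character matrix, haplotypes x markers, rows aligned with
#'   `samples`.
#' @param population free population tag.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(markers, samples, alleles, population = NA_character_) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != nrow(samples))
    stop("one allele row per haplotype row required", call. = FALSE)
  if (ncol(alleles) != nrow(markers))
    stop("allele matrix width must equal marker count", call. = FALSE)
  cnt <- table(samples$sample)
  expected <- ifelse(samples$sex[match(names(cnt), samples$sample)] == "male", 1L, 2L)
  if (any(as.integer(cnt) != expected))
    stop("males must contribute one haplotype, females two", call. = FALSE)
  colnames(alleles) <- markers$id
  structure(list(markers = as.data.frame(markers), samples = as.data.frame(samples),
                 alleles = alleles, population = population),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes (",
      sum(x$samples$sex == "male" & x$samples$hap_index == 1), "male,",
      length(unique(x$samples$sample[x$samples$sex == "female"])), "female ) x",
      nrow(x$markers), "markers;", x$population, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phased haplotype panel from VCF
#'
#' Phased genotypes are required (`|` separator, or a single allele for
#' hemizygous males). Multiallelic and indel records are skipped with a
#' message. Sex is taken from an explicit table, never inferred.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @param sex_table data frame with columns `sample` and `sex`
#'   ("male"/"female"), or a named character vector.
#' @param region optional single-row interval (0-based half-open) restricting
#'   the records read.
#' @param population population tag stored on the panel.
#' @return A `haplotype_panel`. Positions are converted to 0-based.
#' @export
read_phased_panel <- function(path, sex_table, region = NULL,
                              population = NA_character_) {
  if (is.data.frame(sex_table)) {
    sexes <- stats::setNames(as.character(sex_table$sex),
                             as.character(sex_table$sample))
  } else sexes <- sex_table
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos0 <- vcf_to_internal(as.integer(fix[, "POS"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_phased_panel: skipped ", n_skipped,
            " multiallelic/indel record(s)")
  if (!is.null(region)) {
    keep <- keep & fix[, "CHROM"] == region$chrom[1] &
      pos0 >= region$start[1] & pos0 < region$end[1]
  }
  gt <- v@gt
  sample_ids <- colnames(gt)[-1]
  unknown <- setdiff(sample_ids, names(sexes))
  if (length(unknown))
    stop("sex not specified for sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  idx <- which(keep)
  markers <- data.frame(id = ifelse(fix[idx, "ID"] == "." | is.na(fix[idx, "ID"]),
                                    paste0(fix[idx, "CHROM"], ":", fix[idx, "POS"]),
                                    fix[idx, "ID"]),
                        pos = pos0[idx], ref = ref[idx], alt = alt[idx],
                        stringsAsFactors = FALSE)
  samp_rows <- list(); allele_rows <- list(); r <- 0L
  for (s in sample_ids) {
    calls <- if (length(idx)) sub(":.*", "", gt[idx, s]) else character(0)
    if (any(grepl("/", calls, fixed = TRUE)))
      stop("unphased genotype for sample ", s, " at record ",
           which(grepl("/", calls, fixed = TRUE))[1], call. = FALSE)
    parts <- strsplit(calls, "|", fixed = TRUE)
    n_hap <- if (sexes[s] == "male") 1L else 2L
    for (h in seq_len(n_hap)) {
      codes <- vapply(parts, function(p) {
        if (length(p) >= h) p[h] else p[1]
      }, character(1))
      al <- ifelse(codes == "0", markers$ref,
                   ifelse(codes == "1", markers$alt, NA_character_))
      r <- r + 1L
      samp_rows[[r]] <- data.frame(sample = s, sex = sexes[s], hap_index = h,
                                   stringsAsFactors = FALSE)
      allele_rows[[r]] <- al
    }
  }
  samples <- do.call(rbind, samp_rows)
  alleles <- do.call(rbind, allele_rows)
  if (is.null(alleles)) alleles <- matrix(character(0), 0, nrow(markers))
  haplotype_panel(markers, samples, alleles, population)
}

#' Write a phased haplotype panel as VCF
#'
#' Males are written as single-allele hemizygous genotypes, females as
#' pipe-phased diploid genotypes. Positions are converted back to 1-based.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  m <- panel$markers
  sample_ids <- unique(panel$samples$sample)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  chrom <- attr(panel, "chrom") %||% "chrX"
  code <- function(al, j) ifelse(al == m$ref[j], "0", "1")
  rows <- vapply(seq_len(nrow(m)), function(j) {
    gts <- vapply(sample_ids, function(s) {
      ridx <- which(panel$samples$sample == s)
      if (panel$samples$sex[ridx[1]] == "male") {
        code(panel$alleles[ridx[1], j], j)
      } else {
        ridx <- ridx[order(panel$samples$hap_index[ridx])]
        paste(code(panel$alleles[ridx[1], j], j),
              code(panel$alleles[ridx[2], j], j), sep = "|")
      }
    }, character(1))
    paste(c(chrom, internal_to_vcf(m$pos[j]), m$id[j], m$ref[j], m$alt[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct a Y-STR haplotype set
#'
#' @param repeats integer matrix of repeat counts, samples x loci; bilocal
#'   markers occupy two columns.
#' @param mu named numeric vector of per-locus mutation rates
#'   (mutations/locus/generation), names matching `colnames(repeats)`.
#' @param bilocal optional list of length-2 character vectors naming column
#'   pairs that form one bilocal marker (e.g. DYS385a/b) whose two values are
#'   exchangeable.
#' @return An object of class `str_set`.
#' @export
str_haplotype_set <- function(repeats, mu, bilocal = NULL) {
  repeats <- as.matrix(repeats)
  storage.mode(repeats) <- "integer"
  if (is.null(colnames(repeats))) stop("repeat matrix needs locus names", call. = FALSE)
  if (any(repeats <= 0, na.rm = TRUE))
    stop("repeat counts must be positive integers", call. = FALSE)
  missing_mu <- setdiff(colnames(repeats), names(mu))
  if (length(missing_mu))
    stop("no mutation rate for locus/loci: ", paste(missing_mu, collapse = ", "),
         call. = FALSE)
  mu <- mu[colnames(repeats)]
  if (any(mu <= 0 | mu >= 1))
    stop("mutation rates must lie in (0, 1)", call. = FALSE)
  if (!is.null(bilocal)) {
    for (p in bilocal)
      if (length(p) != 2 || !all(p %in% colnames(repeats)))
        stop("each bilocal entry must name two repeat columns", call. = FALSE)
  }
  structure(list(repeats = repeats, mu = mu, bilocal = bilocal),
            class = "str_set")
}

#' Read a Y-STR haplotype table and per-locus mutation rates
#'
#' @param path TSV with a `sample` column and one column per locus.
#' @param mu_path TSV with columns `locus` and `mu`.
#' @param bilocal optional list of column-name pairs; see [str_haplotype_set()].
#' @return An `str_set`.
#' @export
read_str_table <- function(path, mu_path, bilocal = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(tab)) stop("STR table needs a 'sample' column", call. = FALSE)
  reps <- as.matrix(tab[, setdiff(names(tab), "sample"), drop = FALSE])
  rownames(reps) <- tab$sample
  mus <- utils::read.delim(mu_path, stringsAsFactors = FALSE)
  str_haplotype_set(reps, stats::setNames(mus$mu, mus$locus), bilocal = bilocal)
}

#' Write a Y-STR haplotype set to TSV
#'
#' @param strs an `str_set`.
#' @param path output path for the repeat table.
#' @param mu_path optional output path for the mutation-rate table.
#' @return `path`, invisibly.
#' @export
write_str_table <- function(strs, path, mu_path = NULL) {
  tab <- data.frame(sample = rownames(strs$repeats) %||%
                      paste0("s", seq_len(nrow(strs$repeats))),
                    strs$repeats, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mu_path))
    utils::write.table(data.frame(locus = names(strs$mu), mu = unname(strs$mu)),
                       mu_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
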