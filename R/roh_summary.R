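#' Genome specification (chromosome lengths)
#'
#' A table of autosome lengths, the denominator for [froh()].
#'
#' @param chrom chromosome labels (unique).
#' @param length_bp chromosome lengths in bp (> 0).
#' @return a tibble of class `genome_spec` with columns `chrom`, `length_bp`.
#' @export
genome_spec <- function(chrom, length_bp) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) abort("chromosome labels must be unique")
  if (any(length_bp <= 0)) abort("chromosome lengths must be positive")
  out <- tibble(chrom = chrom, length_bp = as.numeric(length_bp))
  class(out) <- c("genome_spec", class(out))
  out
}

#' Read chromosome lengths from a FASTA index (.fai)
#'
#' Uses the first two columns (sequence name, length) of a samtools-style
#' `.fai` file; a leading `"chr"` prefix is stripped from names.
#'
#' @param path path to the `.fai` file.
#' @param autosomes optional chromosome labels to keep, in order.
#' @return a [genome_spec()].
#' @export
read_fai <- function(path, autosomes = NULL) {
  fai <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  chrom <- normalise_chrom(fai[[1]])
  len <- as.numeric(fai[[2]])
  if (!is.null(autosomes)) {
    keep <- match(as.character(autosomes), chrom)
    if (anyNA(keep)) abort("autosome label(s) missing from .fai")
    chrom <- chrom[keep]; len <- len[keep]
  }
  genome_spec(chrom, len)
}

#' Length-class summary of ROH
#'
#' Bins run lengths into Mb classes with left-closed edges
#' `[e1, e2), [e2, e3), ...` and an open-ended last class, and reports
#' per-class counts, exact fractions and display percentages (rounded half
#' away from zero to the nearest integer).
#'
#' @param segments a tibble from [detect_roh()], or a numeric vector of run
#'   lengths in bp.
#' @param edges_mb strictly increasing class edges in Mb; default
#'   `c(0.5, 1, 2, 5)` giving classes 0.5-1, 1-2, 2-5 and >5 Mb.
#' @return a tibble with `class`, `min_mb`, `max_mb`, `n`, `frac`, `pct`;
#'   attribute `n_total` holds the total count. With no segments the
#'   percentages are `NA` (flagged by `frac` being `NaN`).
#' @examples
#' length_class_summary(c(0.7e6, 1.5e6, 1.5e6, 6e6))
#' @export
length_class_summary <- function(segments, edges_mb = c(0.5, 1, 2, 5)) {
  if (is.data.frame(segments)) segments <- segments$length_bp
  if (any(diff(edges_mb) <= 0)) abort("edges_mb must be strictly increasing")
  len_mb <- segments / 1e6
  lo <- edges_mb
  hi <- c(edges_mb[-1], Inf)
  labels <- c(paste0(lo[-length(lo)], "-", hi[-length(hi)], " Mb"),
              paste0(">", lo[length(lo)], " Mb"))
  cls <- cut(len_mb, breaks = c(edges_mb, Inf), right = FALSE, labels = labels)
  if (anyNA(cls) && length(len_mb)) {
    abort("segment length(s) below the first class edge")
  }
  n <- as.integer(table(cls))
  total <- sum(n)
  out <- tibble(
    class = labels, min_mb = lo, max_mb = hi, n = n,
    frac = n / total,
    pct = round_half_away(100 * n / total)
  )
  attr(out, "n_total") <- total
  out
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' For each individual, the total length of its runs of homozygosity divided
#' by the genome length considered: the genomic inbreeding coefficient
#' F_ROH. The default denominator is the sum of autosome lengths in
#' `genome`; `denominator = "snp_span"` instead uses the SNP-spanned length
#' (first to last SNP per chromosome), which requires `sites`.
#'
#' @param segments a tibble from [detect_roh()].
#' @param genome a [genome_spec()].
#' @param individuals sample identifiers to report (zero-filled when absent
#'   from `segments`); defaults to the panel individuals recorded by
#'   [detect_roh()], or to the individuals present in `segments`.
#' @param denominator `"autosome_length"` (default) or `"snp_span"`.
#' @param sites site table (`chrom`, `pos`) for the `"snp_span"` denominator.
#' @return a tibble with `individual`, `total_roh_bp`, `f_roh`.
#' @export
froh <- function(segments, genome, individuals = NULL,
                 denominator = c("autosome_length", "snp_span"),
                 sites = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(genome, "genome_spec"))
  segs <- as_segment_tbl(segments)
  if (nrow(segs)) {
    miss <- setdiff(segs$chrom, genome$chrom)
    if (length(miss)) {
      abort(sprintf("segment chromosome(s) not in genome: %s",
                    paste(miss, collapse = ", ")))
    }
    chk <- left_join(segs, genome, by = "chrom", suffix = c("", "_chrom"))
    if (any(chk$end_pos > chk$length_bp_chrom)) {
      abort("segment extends beyond chromosome length")
    }
  }
  if (is.null(individuals)) {
    individuals <- attr(segments, "individuals") %||% unique(segs$individual)
  }
  denom <- if (denominator == "autosome_length") {
    sum(genome$length_bp)
  } else {
    if (is.null(sites)) abort("`sites` is required for the snp_span denominator")
    sites |>
      group_by(.data$chrom) |>
      summarise(span = max(.data$pos) - min(.data$pos) + 1, .groups = "drop") |>
      pull(.data$span) |>
      sum()
  }
  totals <- segs |>
    group_by(.data$individual) |>
    summarise(total_roh_bp = sum(.data$length_bp), .groups = "drop")
  tibble(individual = as.character(individuals)) |>
    left_join(totals, by = "individual") |>
    mutate(
      total_roh_bp = dplyr::coalesce(.data$total_roh_bp, 0),
      f_roh = .data$total_roh_bp / denom
    )
}

#' Per-chromosome ROH counts
#'
#' Counts runs per chromosome over all individuals, zero-filled for
#' chromosomes of `genome` with no runs.
#'
#' @param segments a tibble from [detect_roh()].
#' @param genome optional [genome_spec()] defining the chromosome universe.
#' @return a tibble with `chrom`, `n_roh`.
#' @export
chromosome_counts <- function(segments, genome = NULL) {
  segs <- as_segment_tbl(segments)
  chroms <- if (!is.null(genome)) genome$chrom else chrom_levels(segs$chrom)
  counts <- segs |> count(.data$chrom, name = "n_roh")
  tibble(chrom = chroms) |>
    left_join(counts, by = "chrom") |>
    mutate(n_roh = dplyr::coalesce(.data$n_roh, 0L))
}
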