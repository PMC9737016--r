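#' Load gene intervals from BED or GFF3
#'
#' Reads gene-level intervals for island annotation. BED input (0-based
#' half-open) is converted to 1-based inclusive coordinates; GFF3 input is
#' restricted to records of type `gene` (a file with no gene records yields
#' an empty table with a warning). Chromosome labels are normalised by
#' stripping a leading `"chr"` prefix. Gzipped files are accepted.
#'
#' @param path path to a BED4+ or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return a tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene_id`, `gene_name`, `biotype`.
#' @export
load_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed"
      else if (grepl("\\.(gff3?|gff)$", base, ignore.case = TRUE)) "gff3"
      else abort("cannot infer format from extension; pass `format`")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) abort(sprintf("failed to parse %s: %s", path,
                                      conditionMessage(e)))
  )
  md <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(md)) return(as.character(md[[nm]]))
    rep(NA_character_, length(gr))
  }
  out <- tibble(
    chrom = normalise_chrom(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = pick("ID", "gene_id", "name"),
    gene_name = pick("Name", "gene_name", "name"),
    biotype = pick("gene_biotype", "biotype")
  )
  if (format == "gff3") {
    type <- as.character(md$type)
    out <- out[!is.na(type) & type == "gene", , drop = FALSE]
    if (!nrow(out)) warn("no records of type 'gene' found in GFF3")
  }
  if (nrow(out) && any(out$start > out$end)) abort("interval with start > end")
  out
}

#' Overlap islands with gene intervals
#'
#' Interval-overlap join (at least 1 bp, 1-based inclusive coordinates on
#' both sides): every gene overlapping each island is reported.
#'
#' @param islands a tibble from [call_islands()] (columns `chrom`,
#'   `start_pos`, `end_pos`).
#' @param genes a tibble from [load_gene_intervals()].
#' @return a tibble with one row per (island, gene) overlap: the island
#'   columns plus `gene_id`, `gene_name`, `biotype`, `gene_start`,
#'   `gene_end`.
#' @export
overlap_genes <- function(islands, genes) {
  islands <- as_segment_tbl(islands)
  genes <- as_segment_tbl(genes)
  if (!nrow(islands) || !nrow(genes)) {
    return(mutate(islands[0, ], gene_id = character(),
                  gene_name = character(), biotype = character(),
                  gene_start = integer(), gene_end = integer()))
  }
  gr_isl <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start_pos, islands$end_pos)
  )
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  # disjoint chromosome sets between islands and genes are a valid empty join
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_isl, gr_gene))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dplyr::bind_cols(
    islands[qi, , drop = FALSE],
    tibble(
      gene_id = genes$gene_id[si],
      gene_name = genes$gene_name[si],
      biotype = genes$biotype[si],
      gene_start = genes$start[si],
      gene_end = genes$end[si]
    )
  )
}

#' Annotate islands with comma-separated gene lists
#'
#' One row per island with overlapping gene names collapsed into a single
#' string (`"None"` when no gene overlaps), mirroring the usual reporting
#' table for significant regions.
#'
#' @inheritParams overlap_genes
#' @return the `islands` tibble plus `candidate_genes` and `n_genes`.
#' @export
annotate_islands <- function(islands, genes) {
  islands <- as_tibble(islands)
  ov <- overlap_genes(islands, genes)
  key <- paste(islands$chrom, islands$start_pos, islands$end_pos)
  gene_of <- ov |>
    mutate(key = paste(.data$chrom, .data$start_pos, .data$end_pos),
           label = dplyr::coalesce(.data$gene_name, .data$gene_id)) |>
    group_by(.data$key) |>
    summarise(candidate_genes = paste(unique(.data$label), collapse = ", "),
              n_genes = dplyr::n_distinct(.data$label), .groups = "drop")
  islands |>
    mutate(key = key) |>
    left_join(gene_of, by = "key") |>
    mutate(
      candidate_genes = dplyr::coalesce(.data$candidate_genes, "None"),
      n_genes = dplyr::coalesce(.data$n_genes, 0L)
    ) |>
    select(-"key")
}
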