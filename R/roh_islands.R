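#' Island-calling parameters
#'
#' @param incidence_threshold fraction of individuals whose ROH must cover a
#'   SNP for it to count as significant; strict `>` (with 30 individuals,
#'   "more than 30%" means at least 10).
#' @param cluster_max_gap_bp maximum distance between consecutive
#'   significant SNPs within one island; larger gaps split islands.
#' @return a list of class `island_params`.
#' @export
island_params <- function(incidence_threshold = 0.30,
                          cluster_max_gap_bp = 250000) {
  stopifnot(incidence_threshold > 0, incidence_threshold < 1,
            cluster_max_gap_bp >= 1)
  structure(
    list(incidence_threshold = incidence_threshold,
         cluster_max_gap_bp = as.numeric(cluster_max_gap_bp)),
    class = "island_params"
  )
}

#' Per-SNP ROH incidence across individuals
#'
#' For every SNP site, counts the number of distinct individuals having at
#' least one run of homozygosity covering the site (`start_pos <= pos <=
#' end_pos` on the same chromosome).
#'
#' @param segments a tibble from [detect_roh()].
#' @param sites site table with `chrom`, `pos`, sorted by position within
#'   chromosome.
#' @param n_individuals number of individuals in the panel (the incidence
#'   denominator); defaults to the panel size recorded by [detect_roh()].
#' @return a tibble of class `incidence_track`: `chrom`, `pos`, `k`,
#'   `incidence`.
#' @export
snp_incidence <- function(segments, sites, n_individuals = NULL) {
  if (is.null(n_individuals)) {
    n_individuals <- length(attr(segments, "individuals"))
    if (!n_individuals) abort("supply `n_individuals`")
  }
  segs <- as_segment_tbl(segments)
  sites <- as_segment_tbl(sites)
  k <- integer(nrow(sites))
  idx_by_chrom <- split(seq_len(nrow(sites)),
                        factor(sites$chrom, unique(sites$chrom)))
  for (ch in intersect(unique(segs$chrom), names(idx_by_chrom))) {
    idx <- idx_by_chrom[[ch]]
    pos <- sites$pos[idx]
    ss <- segs[segs$chrom == ch, ]
    # one individual's runs are disjoint, so each covered site is counted once
    i1 <- findInterval(ss$start_pos - 0.5, pos) + 1L
    i2 <- findInterval(ss$end_pos, pos)
    for (r in seq_len(nrow(ss))) {
      if (i2[r] >= i1[r]) {
        rng <- idx[i1[r]:i2[r]]
        k[rng] <- k[rng] + 1L
      }
    }
  }
  out <- tibble(chrom = sites$chrom, pos = sites$pos, k = k,
                incidence = k / n_individuals)
  attr(out, "n_individuals") <- n_individuals
  class(out) <- c("incidence_track", class(out))
  out
}

#' Call ROH islands from an incidence track
#'
#' Significant SNPs (incidence strictly above the threshold) are grouped
#' into maximal clusters in which consecutive significant SNPs on the same
#' chromosome are at most `cluster_max_gap_bp` apart. Island boundaries are
#' the outermost significant SNP positions.
#'
#' @param track a tibble from [snp_incidence()].
#' @param params an [island_params()].
#' @return a tibble of class `roh_islands`: `chrom`, `start_pos`, `end_pos`,
#'   `n_snp`, `length_kb`, `peak_incidence`.
#' @export
call_islands <- function(track, params = island_params()) {
  sig <- as_segment_tbl(track) |>
    filter(.data$incidence > params$incidence_threshold)
  if (!nrow(sig)) {
    out <- tibble(chrom = character(), start_pos = integer(),
                  end_pos = integer(), n_snp = integer(),
                  length_kb = numeric(), peak_incidence = numeric())
  } else {
    sig <- sig |>
      mutate(
        new_cluster = dplyr::row_number() == 1 |
          .data$chrom != dplyr::lag(.data$chrom) |
          .data$pos - dplyr::lag(.data$pos) > params$cluster_max_gap_bp,
        cluster = cumsum(.data$new_cluster)
      )
    out <- sig |>
      group_by(.data$cluster) |>
      summarise(
        chrom = .data$chrom[1],
        start_pos = min(.data$pos),
        end_pos = max(.data$pos),
        n_snp = dplyr::n(),
        peak_incidence = max(.data$incidence),
        .groups = "drop"
      ) |>
      mutate(length_kb = island_length_kb(.data$start_pos, .data$end_pos)) |>
      select("chrom", "start_pos", "end_pos", "n_snp", "length_kb",
             "peak_incidence")
  }
  class(out) <- c("roh_islands", class(out))
  out
}

#' Island length in kb
#'
#' Inclusive length `(end - start + 1)` in kb, rounded half away from zero
#' to the nearest integer — the convention used for reported region sizes.
#'
#' @param start_pos,end_pos 1-based positions of the first and last
#'   significant SNP.
#' @return integer kb (vectorised).
#' @examples
#' island_length_kb(11474883, 12369497)  # 895
#' @export
island_length_kb <- function(start_pos, end_pos) {
  round_half_away((end_pos - start_pos + 1) / 1000)
}

#' Write an incidence track as TSV or BedGraph
#'
#' @param track a tibble from [snp_incidence()].
#' @param path output path.
#' @param format `"tsv"` or `"bedgraph"` (per-SNP 1-bp intervals carrying
#'   the incidence).
#' @return `path`, invisibly.
#' @export
write_incidence <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(track), path)
  } else {
    bg <- tibble(chrom = track$chrom, start = track$pos - 1L,
                 end = track$pos, value = track$incidence)
    readr::write_tsv(bg, path, col_names = FALSE)
  }
  invisible(path)
}

#' Write islands as TSV or BED
#'
#' The TSV mirrors the usual reporting columns (Chr, Start, End, Kb,
#' N of SNPs); BED is 0-based half-open.
#'
#' @param islands a tibble from [call_islands()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_islands <- function(islands, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- tibble(
      Chr = islands$chrom, Start = islands$start_pos, End = islands$end_pos,
      Kb = islands$length_kb, `N of SNPs` = islands$n_snp
    )
    readr::write_tsv(out, path)
  } else {
    bed <- tibble(chrom = islands$chrom, start = islands$start_pos - 1L,
                  end = islands$end_pos)
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
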