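#' Parameters for the sliding-window ROH scan
#'
#' The full parameterisation of the window scan and run filters. Defaults
#' are the standard resequencing configuration: a 50-SNP window allowing at
#' most one heterozygote and five missing calls; a SNP enters a run when at
#' least 5% of the windows covering it are homozygous; a run must contain at
#' least 100 SNPs, span at least 500 kb, keep a density of at least one SNP
#' per 50 kb, and contain no inter-SNP gap above 100 kb.
#'
#' @param window_size number of SNPs per sliding window.
#' @param max_het_in_window maximum heterozygous calls tolerated per window.
#' @param max_missing_in_window maximum missing calls tolerated per window.
#' @param window_pass_threshold minimum proportion of homozygous covering
#'   windows for a SNP to be flagged (inclusive, `>=`).
#' @param min_snp_in_run minimum SNPs per reported run.
#' @param min_length_bp minimum run length in bp (`end - start + 1`).
#' @param max_kb_per_snp maximum kb of run length per contained SNP
#'   (50 means at least 1 SNP per 50 kb).
#' @param max_gap_bp maximum gap between consecutive flagged SNPs inside a
#'   run; larger gaps split the run.
#' @param edge_mode `"shrink"` (default): near chromosome ends the covering-
#'   window denominator shrinks to the number of windows that actually exist;
#'   `"skip"`: the denominator stays at the full window count, so edge SNPs
#'   need proportionally more homozygous windows.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(window_size = 50,
                       max_het_in_window = 1,
                       max_missing_in_window = 5,
                       window_pass_threshold = 0.05,
                       min_snp_in_run = 100,
                       min_length_bp = 500000,
                       max_kb_per_snp = 50,
                       max_gap_bp = 100000,
                       edge_mode = c("shrink", "skip")) {
  stopifnot(
    window_size >= 1,
    max_het_in_window >= 0, max_missing_in_window >= 0,
    window_pass_threshold >= 0, window_pass_threshold <= 1,
    min_snp_in_run >= 1, min_length_bp >= 1,
    max_kb_per_snp > 0, max_gap_bp >= 1
  )
  structure(
    list(
      window_size = as.integer(window_size),
      max_het_in_window = as.integer(max_het_in_window),
      max_missing_in_window = as.integer(max_missing_in_window),
      window_pass_threshold = window_pass_threshold,
      min_snp_in_run = as.integer(min_snp_in_run),
      min_length_bp = as.numeric(min_length_bp),
      max_kb_per_snp = as.numeric(max_kb_per_snp),
      max_gap_bp = as.numeric(max_gap_bp),
      edge_mode = match.arg(edge_mode)
    ),
    class = "roh_params"
  )
}

#' Is a genotype window homozygous?
#'
#' A window is homozygous when it contains no more than the allowed number
#' of heterozygous calls and no more than the allowed number of missing
#' calls.
#'
#' @param codes integer genotype codes for one window.
#' @param params a [roh_params()].
#' @return logical scalar.
#' @export
window_is_homozygous <- function(codes, params = roh_params()) {
  sum(codes == 1L) <= params$max_het_in_window &&
    sum(codes == -1L) <= params$max_missing_in_window
}

#' Per-SNP homozygosity flags from the sliding-window scan
#'
#' Slides a `window_size`-SNP window along one chromosome of one individual
#' and flags each SNP by the proportion of covering windows that are
#' homozygous. For SNP `i` of `n`, the covering windows start at
#' `max(1, i - window_size + 1) ... min(i, n - window_size + 1)`; a
#' chromosome shorter than the window is scanned with a single truncated
#' window covering all its SNPs. The SNP passes when the homozygous
#' proportion reaches `window_pass_threshold` (inclusive).
#'
#' @param codes integer genotype codes of one individual along one
#'   chromosome, in position order.
#' @param params a [roh_params()].
#' @return logical vector, one flag per SNP.
#' @export
snp_pass_flags <- function(codes, params = roh_params()) {
  n <- length(codes)
  if (n == 0) return(logical(0))
  w <- min(params$window_size, n)
  nw <- n - w + 1L
  hom <- (roll_sum(codes == 1L, w) <= params$max_het_in_window) &
    (roll_sum(codes == -1L, w) <= params$max_missing_in_window)
  cs <- c(0, cumsum(hom))
  i <- seq_len(n)
  first <- pmax(1L, i - w + 1L)
  last <- pmin(i, nw)
  n_hom <- cs[last + 1L] - cs[first]
  n_win <- if (params$edge_mode == "shrink") last - first + 1L else w
  n_hom / n_win >= params$window_pass_threshold
}

#' Assemble candidate runs from per-SNP flags
#'
#' Groups maximal stretches of consecutively flagged SNPs, splitting
#' wherever the distance between adjacent flagged SNPs exceeds
#' `max_gap_bp`.
#'
#' @param flags logical vector from [snp_pass_flags()].
#' @param pos integer positions aligned to `flags` (one chromosome).
#' @param params a [roh_params()].
#' @return a tibble of candidates: `start_pos`, `end_pos`, `n_snp`,
#'   `length_bp`.
#' @export
assemble_candidate_runs <- function(flags, pos, params = roh_params()) {
  stopifnot(length(flags) == length(pos))
  idx <- which(flags)
  if (!length(idx)) {
    return(tibble(start_pos = integer(), end_pos = integer(),
                  n_snp = integer(), length_bp = numeric()))
  }
  # new run when the flagged SNP is not adjacent or the gap is too large
  brk <- c(TRUE, diff(idx) != 1L | diff(pos[idx]) > params$max_gap_bp)
  run <- cumsum(brk)
  tibble(idx = idx, run = run, pos = pos[idx]) |>
    group_by(.data$run) |>
    summarise(
      start_pos = min(.data$pos),
      end_pos = max(.data$pos),
      n_snp = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(length_bp = .data$end_pos - .data$start_pos + 1) |>
    select(-"run")
}

#' Filter candidate runs into reported ROH
#'
#' Keeps candidates that contain enough SNPs, are long enough, and are dense
#' enough (`length_bp <= n_snp * max_kb_per_snp * 1000`).
#'
#' @param candidates tibble from [assemble_candidate_runs()].
#' @param params a [roh_params()].
#' @return the filtered tibble.
#' @export
filter_runs <- function(candidates, params = roh_params()) {
  filter(
    candidates,
    .data$n_snp >= params$min_snp_in_run,
    .data$length_bp >= params$min_length_bp,
    .data$length_bp <= .data$n_snp * params$max_kb_per_snp * 1000
  )
}

#' Detect runs of homozygosity in a genotype panel
#'
#' Runs the sliding-window scan ([snp_pass_flags()]), run assembly
#' ([assemble_candidate_runs()]) and run filtering ([filter_runs()]) for
#' every individual on every chromosome. The output is deterministic:
#' identical input yields an identical segment table.
#'
#' @param panel a [genotype_panel()] with sites sorted by position.
#' @param params a [roh_params()].
#' @return a tibble of class `roh_segments` with one row per run:
#'   `individual`, `chrom`, `start_pos`, `end_pos`, `n_snp`, `length_bp`.
#' @examples
#' sim <- simulate_panel(sim_preset_small(seed = 42))
#' roh <- detect_roh(sim$panel)
#' head(roh)
#' @export
detect_roh <- function(panel, params = roh_params()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(params, "roh_params"))
  chroms <- unique(panel$sites$chrom)
  idx_by_chrom <- split(seq_len(nrow(panel$sites)),
                        factor(panel$sites$chrom, chroms))
  out <- purrr::map(panel$individuals, function(ind) {
    row <- panel$genotypes[ind, ]
    purrr::map(chroms, function(ch) {
      idx <- idx_by_chrom[[ch]]
      flags <- snp_pass_flags(row[idx], params)
      runs <- assemble_candidate_runs(flags, panel$sites$pos[idx], params)
      runs <- filter_runs(runs, params)
      if (nrow(runs)) mutate(runs, individual = ind, chrom = ch) else NULL
    }) |> bind_rows()
  }) |> bind_rows()
  if (!nrow(out)) {
    out <- tibble(individual = character(), chrom = character(),
                  start_pos = integer(), end_pos = integer(),
                  n_snp = integer(), length_bp = numeric())
  } else {
    out <- out |>
      select("individual", "chrom", "start_pos", "end_pos", "n_snp", "length_bp") |>
      arrange(
        match(.data$individual, panel$individuals),
        match(.data$chrom, chroms), .data$start_pos
      )
  }
  class(out) <- c("roh_segments", class(out))
  attr(out, "individuals") <- panel$individuals
  attr(out, "params") <- params
  out
}

#' Write ROH segments as TSV or BED
#'
#' The BED output is 0-based half-open (`start_pos - 1`, `end_pos`) with the
#' individual in the name column.
#'
#' @param segments a tibble from [detect_roh()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(segments), path)
  } else {
    bed <- tibble(
      chrom = segments$chrom,
      start = segments$start_pos - 1L,
      end = segments$end_pos,
      name = segments$individual
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
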