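#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (`round()` in base R rounds
#' ties to even). Used for all displayed kb and percentage figures so that
#' printed summaries match conventional reporting.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal digits to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# order chromosome labels numerically where possible, others after
chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

# rolling sum of a logical/numeric vector over windows of width w
roll_sum <- function(x, w) {
  cs <- cumsum(x)
  if (w >= length(x)) return(cs[length(x)])
  cs[w:length(x)] - c(0, cs[seq_len(length(x) - w)])
}

# strip a leading "chr" prefix (VCF dialect variation)
normalise_chrom <- function(x) sub("^chr", "", as.character(x))

# coerce externally loaded tables (e.g. TSV re-imports) to canonical types
as_segment_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  if ("chrom" %in% names(x)) x$chrom <- as.character(x$chrom)
  if ("individual" %in% names(x)) x$individual <- as.character(x$individual)
  x
}
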