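#' Construct a genotype panel
#'
#' A genotype panel holds an individuals-by-sites matrix of diploid genotype
#' codes together with the site table. Codes are `0` (homozygous reference),
#' `1` (heterozygous), `2` (homozygous alternate) and `-1` (missing). Sites
#' are biallelic SNPs, strictly increasing in position within each chromosome.
#'
#' @param genotypes integer matrix, individuals in rows, sites in columns,
#'   entries in `{-1, 0, 1, 2}`.
#' @param sites data frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (single-nucleotide strings) and optionally `qual`
#'   (site quality, `NA` when absent).
#' @param individuals character vector of sample identifiers; defaults to the
#'   row names of `genotypes`.
#' @return an object of class `genotype_panel`: a list with elements
#'   `genotypes`, `sites` (tibble) and `individuals`.
#' @seealso [read_vcf()], [simulate_panel()]
#' @examples
#' g <- rbind(a = c(0L, 1L), b = c(2L, -1L))
#' sites <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
#' genotype_panel(g, sites)
#' @export
genotype_panel <- function(genotypes, sites, individuals = rownames(genotypes)) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  sites <- as_tibble(sites)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, ref, alt")
  }
  if (!"qual" %in% names(sites)) sites$qual <- NA_real_
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(genotypes)))
  individuals <- as.character(individuals)

  if (nrow(genotypes) != length(individuals)) {
    abort("genotype matrix rows must match number of individuals")
  }
  if (ncol(genotypes) != nrow(sites)) {
    abort("genotype matrix columns must match number of sites")
  }
  bad <- !genotypes %in% c(-1L, 0L, 1L, 2L)
  if (any(bad)) abort("genotype codes must be in {-1, 0, 1, 2}")
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1L)) abort("positions must be >= 1")
    if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L) ||
        any(sites$ref == sites$alt)) {
      abort("sites must be biallelic SNPs (single-base ref != alt)")
    }
    ord <- unname(split(sites$pos, factor(sites$chrom, unique(sites$chrom))))
    if (any(vapply(ord, function(p) any(diff(p) <= 0), logical(1)))) {
      abort("site positions must be strictly increasing within chromosome")
    }
  }
  rownames(genotypes) <- individuals
  structure(
    list(genotypes = genotypes, sites = sites, individuals = individuals),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d sites on %d chromosome(s)\n",
    length(x$individuals), nrow(x$sites), length(unique(x$sites$chrom))
  ))
  miss <- if (length(x$genotypes)) mean(x$genotypes == -1L) else NA_real_
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Tidy a genotype panel into its site table
#'
#' Returns one row per SNP site with per-site call counts, ready for joins
#' with per-site statistics.
#'
#' @param x a [genotype_panel()].
#' @param ... unused.
#' @return a tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `n_called`, `n_missing`.
#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  g <- x$genotypes
  x$sites |>
    mutate(
      n_called = colSums(g != -1L),
      n_missing = colSums(g == -1L)
    )
}

#' One-row summary of a genotype panel
#'
#' @param x a [genotype_panel()].
#' @param ... unused.
#' @return a tibble with panel dimensions, missingness and mean heterozygosity.
#' @method glance genotype_panel
#' @export
glance.genotype_panel <- function(x, ...) {
  g <- x$genotypes
  called <- sum(g != -1L)
  tibble(
    n_individuals = length(x$individuals),
    n_sites = nrow(x$sites),
    n_chromosomes = length(unique(x$sites$chrom)),
    missing_rate = if (length(g)) mean(g == -1L) else NA_real_,
    mean_het = if (called > 0) sum(g == 1L) / called else NA_real_
  )
}

# subset a panel to a logical/integer site index, preserving order
subset_sites <- function(panel, keep) {
  genotype_panel(
    panel$genotypes[, keep, drop = FALSE],
    panel$sites[keep, , drop = FALSE],
    panel$individuals
  )
}
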