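#' Per-site diversity statistics
#'
#' For every SNP site, computes the alternate-allele frequency, minor allele
#' frequency, and per-site nucleotide diversity
#' \deqn{\pi = \frac{n}{n-1}\left(1 - \sum_i x_i^2\right)}
#' where \eqn{n} is the number of non-missing allele copies at the site and
#' \eqn{x_i} the observed frequency of allele \eqn{i}. This equals the mean
#' pairwise difference over all \eqn{n(n-1)/2} pairs of allele copies.
#' Missing genotypes are excluded from the denominators. Sites with fewer
#' than two called allele copies get `NA` diversity and are flagged.
#'
#' @param panel a [genotype_panel()].
#' @return a tibble with one row per site: `chrom`, `pos`, `maf`, `pi`,
#'   `n_sequences` (non-missing allele copies), `alt_freq`, and a logical
#'   `flagged` marking undefined values.
#' @examples
#' g <- rbind(c(0L, 1L, 2L), c(1L, 1L, 2L))
#' p <- genotype_panel(g, data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "C"))
#' site_diversity(p)
#' @export
site_diversity <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  n_called <- colSums(g != -1L)
  alt <- colSums(g == 1L) + 2L * colSums(g == 2L)
  n_seq <- 2L * n_called
  p <- ifelse(n_seq > 0, alt / n_seq, NA_real_)
  pi <- ifelse(n_seq >= 2,
               (n_seq / (n_seq - 1)) * (1 - p^2 - (1 - p)^2),
               NA_real_)
  panel$sites |>
    select("chrom", "pos") |>
    mutate(
      maf = pmin(p, 1 - p),
      pi = pi,
      n_sequences = as.integer(n_seq),
      alt_freq = p,
      flagged = n_seq < 2
    )
}

#' Per-individual observed heterozygosity
#'
#' The fraction of an individual's called (non-missing) genotypes that are
#' heterozygous. Individuals with no called genotypes get `NA` and are
#' flagged.
#'
#' @param panel a [genotype_panel()].
#' @return a tibble with `individual`, `ho`, `n_called`, `flagged`.
#' @export
individual_het <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  n_called <- unname(rowSums(g != -1L))
  tibble(
    individual = panel$individuals,
    ho = ifelse(n_called > 0, unname(rowSums(g == 1L)) / n_called, NA_real_),
    n_called = as.integer(n_called),
    flagged = n_called == 0
  )
}

#' Genomic relationship matrix (GCTA estimator)
#'
#' Pairwise relatedness from genome-wide SNPs with allele-frequency
#' standardised genotypes, the estimator of Yang et al. (2010) as implemented
#' in GCTA. With genotype dosage \eqn{x_{ij} \in \{0,1,2\}} and sample
#' alternate-allele frequency \eqn{p_i} at site \eqn{i}:
#' off-diagonal
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i
#'   \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' and diagonal
#' \deqn{A_{jj} = 1 + \frac{1}{N_{jj}} \sum_i
#'   \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}.}
#' Allele frequencies are computed from the analysed panel itself.
#' Monomorphic sites are excluded; missing genotypes are handled
#' pairwise-complete, with \eqn{N_{jk}} the number of sites where both
#' members of the pair are called. Pairs with no jointly called site get
#' `NA` (flagged in [tidy.roh_grm()]).
#'
#' @param panel a [genotype_panel()].
#' @return an object of class `roh_grm`: list with `A` (relatedness matrix),
#'   `n_sites` (per-pair site counts) and `individuals`.
#' @export
relatedness_matrix <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$individuals) < 2) abort("need at least 2 individuals")
  g <- panel$genotypes
  called <- g != -1L
  n_called <- colSums(called)
  alt <- colSums(g == 1L) + 2L * colSums(g == 2L)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(poly)) abort("no polymorphic sites available")

  x <- g[, poly, drop = FALSE]
  p <- p[poly]
  m <- called[, poly, drop = FALSE]
  denom <- 2 * p * (1 - p)

  u <- sweep(x, 2, 2 * p)          # x - 2p
  u <- sweep(u, 2, sqrt(denom), "/")
  u[!m] <- 0
  num <- tcrossprod(u)             # sum over sites of standardized products
  nn <- tcrossprod(m * 1)          # pairwise-complete site counts
  A <- ifelse(nn > 0, num / nn, NA_real_)

  # diagonal uses its own estimator
  dnum <- x^2 - sweep(x, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(x), ncol(x), byrow = TRUE)
  dnum <- sweep(dnum, 2, denom, "/")
  dnum[!m] <- 0
  diag(A) <- 1 + rowSums(dnum) / diag(nn)

  dimnames(A) <- list(panel$individuals, panel$individuals)
  dimnames(nn) <- dimnames(A)
  structure(
    list(A = A, n_sites = nn, individuals = panel$individuals),
    class = "roh_grm"
  )
}

#' @export
print.roh_grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat(sprintf(
    "<roh_grm> %d individuals; mean off-diagonal %.4f, mean diagonal %.4f\n",
    length(x$individuals), mean(off, na.rm = TRUE),
    mean(diag(x$A), na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy a relatedness matrix into pair rows
#'
#' @param x an object from [relatedness_matrix()].
#' @param ... unused.
#' @return a tibble with one row per ordered pair (upper triangle plus
#'   diagonal): `id1`, `id2`, `relatedness`, `n_sites`, `flagged`.
#' @method tidy roh_grm
#' @export
tidy.roh_grm <- function(x, ...) {
  idx <- which(upper.tri(x$A, diag = TRUE), arr.ind = TRUE)
  tibble(
    id1 = x$individuals[idx[, 1]],
    id2 = x$individuals[idx[, 2]],
    relatedness = x$A[idx],
    n_sites = as.integer(x$n_sites[idx]),
    flagged = is.na(x$A[idx])
  )
}

#' @method glance roh_grm
#' @export
glance.roh_grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  tibble(
    n_individuals = length(x$individuals),
    mean_off_diagonal = mean(off, na.rm = TRUE),
    median_off_diagonal = stats::median(off, na.rm = TRUE),
    mean_diagonal = mean(diag(x$A), na.rm = TRUE)
  )
}

#' Write a relatedness matrix as square TSV
#'
#' @param grm an object from [relatedness_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  df <- as.data.frame(grm$A)
  df <- cbind(id = grm$individuals, df)
  readr::write_tsv(df, path)
  invisible(path)
}
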