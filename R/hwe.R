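#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test of HWE for one biallelic site, using the conditional
#' (Levene) distribution of the heterozygote count given the observed allele
#' counts. The p-value is the total probability of all heterozygote
#' configurations no more probable than the observed one — the convention of
#' Wigginton, Cutler and Abecasis (2005) used by common genotype-QC tools.
#' A monomorphic site cannot deviate and returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative integers,
#'   each argument may be a vector; they are recycled together).
#' @return p-value(s) in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration, p = 1
#' hwe_exact_test(0, 10, 0)    # excess heterozygosity
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- vapply(
    seq_len(max(length(n_hom_ref), length(n_het), length(n_hom_alt))),
    function(i) {
      hwe_exact_one(
        n_hom_ref[[(i - 1) %% length(n_hom_ref) + 1]],
        n_het[[(i - 1) %% length(n_het) + 1]],
        n_hom_alt[[(i - 1) %% length(n_hom_alt) + 1]]
      )
    },
    numeric(1)
  )
  n
}

hwe_exact_one <- function(aa, ab, bb) {
  if (any(c(aa, ab, bb) < 0) || anyNA(c(aa, ab, bb))) {
    abort("genotype counts must be non-negative")
  }
  n <- aa + ab + bb
  if (n < 1) abort("at least one genotyped individual is required")
  n_a <- 2L * aa + ab
  n_b <- 2L * bb + ab
  rare <- min(n_a, n_b)
  common <- max(n_a, n_b)
  if (rare == 0L) return(1.0)
  # heterozygote counts share the parity of the rare allele count
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log Levene probability up to an additive constant
  lp <- hs * log(2) - lgamma(hs + 1) -
    lgamma((rare - hs) / 2 + 1) - lgamma((common - hs) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(ab, hs)]
  p <- sum(pr[pr <= obs * (1 + 1e-9)])
  min(p, 1.0)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test against expected HWE genotype
#' proportions; offered as a faster alternative to [hwe_exact_test()] for
#' large panels. No continuity correction.
#'
#' @inheritParams hwe_exact_test
#' @return p-value(s) in `[0, 1]`.
#' @export
hwe_chisq_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  q <- 1 - p
  exp_counts <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  obs <- cbind(n_hom_ref, n_het, n_hom_alt)
  stat <- rowSums((obs - exp_counts)^2 / exp_counts)
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[p == 0 | q == 0] <- 1.0
  out
}
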