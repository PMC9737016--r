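# Independent brute-force oracles and small-fixture builders used across the
# suite. These deliberately avoid the package's optimized code paths.

# build a panel from a genotype matrix on one or more chromosomes
make_panel <- function(g, pos = NULL, chrom = NULL) {
  g <- as.matrix(g)
  n_site <- ncol(g)
  if (is.null(pos)) pos <- seq_len(n_site) * 1000L
  if (is.null(chrom)) chrom <- rep("1", n_site)
  genotype_panel(
    g,
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
    individuals = paste0("s", seq_len(nrow(g)))
  )
}

# exact HWE p-value by direct factorial enumeration of the Levene
# distribution: P(n_het = h | allele counts) computed from the closed-form
# multinomial/hypergeometric expression, all configurations summed whose
# probability does not exceed the observed one.
brute_hwe <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na_ <- 2 * aa + ab
  nb_ <- 2 * bb + ab
  if (min(na_, nb_) == 0) return(1.0)
  hs <- seq(min(na_, nb_) %% 2, min(na_, nb_), by = 2)
  prob_h <- vapply(hs, function(h) {
    haa <- (na_ - h) / 2
    hbb <- (nb_ - h) / 2
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2) + lfactorial(na_) + lfactorial(nb_) -
          lfactorial(2 * n))
  }, numeric(1))
  obs <- prob_h[hs == ab]
  sum(prob_h[prob_h <= obs * (1 + 1e-9)])
}

# mean pairwise allele difference at one site by enumerating every pair of
# non-missing allele copies
brute_pi <- function(codes) {
  alleles <- unlist(lapply(codes[codes != -1L], function(g) {
    switch(as.character(g), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  }))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  pairs <- combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# per-SNP pass flags by enumerating every window explicitly
brute_flags <- function(codes, params) {
  n <- length(codes)
  w <- min(params$window_size, n)
  starts <- seq_len(n - w + 1)
  hom <- vapply(starts, function(s) {
    win <- codes[s:(s + w - 1)]
    sum(win == 1L) <= params$max_het_in_window &&
      sum(win == -1L) <= params$max_missing_in_window
  }, logical(1))
  vapply(seq_len(n), function(i) {
    cover <- starts[starts <= i & starts + w - 1 >= i]
    n_hom <- sum(hom[match(cover, starts)])
    denom <- if (params$edge_mode == "shrink") length(cover) else w
    n_hom / denom >= params$window_pass_threshold
  }, logical(1))
}

# all-pairs interval overlap join (1-based inclusive)
brute_overlap <- function(islands, genes) {
  hits <- list()
  for (i in seq_len(nrow(islands))) {
    for (j in seq_len(nrow(genes))) {
      if (islands$chrom[i] == genes$chrom[j] &&
          islands$start_pos[i] <= genes$end[j] &&
          genes$start[j] <= islands$end_pos[i]) {
        hits[[length(hits) + 1]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}
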