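test_that("site MAF counts allele copies over non-missing genotypes", {
  # 10 individuals: five hom-ref, three het, two hom-alt -> 7/20 alt copies
  g <- matrix(c(rep(0L, 5), rep(1L, 3), rep(2L, 2)), ncol = 1)
  d <- site_diversity(make_panel(g))
  expect_equal(d$maf, 0.35)
  expect_equal(d$alt_freq, 0.35)
  expect_equal(d$n_sequences, 20L)

  # all hom-ref -> 0; balanced -> 0.5
  d2 <- site_diversity(make_panel(cbind(rep(0L, 6), c(0L, 0L, 1L, 1L, 2L, 2L))))
  expect_equal(d2$maf, c(0, 0.5))
  # missing genotypes shrink the denominator
  d3 <- site_diversity(make_panel(matrix(c(2L, -1L, 0L, -1L), ncol = 1)))
  expect_equal(d3$n_sequences, 4L)
  expect_equal(d3$alt_freq, 0.5)
})

test_that("per-site pi matches hand-computed values and is 0 iff monomorphic", {
  # n = 4 sequences at 0.5/0.5 -> (4/3)(1 - 0.5) = 2/3
  d <- site_diversity(make_panel(matrix(c(0L, 2L), ncol = 1)))
  expect_equal(d$pi, 2 / 3)
  # n = 60 sequences, alt frequency 0.1 -> (60/59)(1 - 0.82)
  g <- matrix(c(rep(1L, 6), rep(0L, 24)), ncol = 1)  # 6/60 alt copies = 0.1
  d2 <- site_diversity(make_panel(g))
  expect_equal(d2$pi, (60 / 59) * (1 - 0.1^2 - 0.9^2))
  expect_equal(d2$pi, 0.18305, tolerance = 1e-4)
  # monomorphic -> exactly 0
  expect_equal(site_diversity(make_panel(matrix(rep(2L, 5), ncol = 1)))$pi, 0)
})

test_that("pi equals the exhaustive pairwise-difference oracle on random panels", {
  set.seed(21)
  for (rep in 1:20) {
    n_ind <- sample(2:8, 1)
    n_site <- sample(3:10, 1)
    g <- matrix(sample(c(-1L, 0L, 1L, 2L), n_ind * n_site, replace = TRUE),
                nrow = n_ind)
    d <- site_diversity(make_panel(g))
    oracle <- apply(g, 2, brute_pi)
    expect_equal(d$pi, oracle)
    ok <- !is.na(d$pi)
    expect_true(all(d$maf[ok] >= 0 & d$maf[ok] <= 0.5))
    expect_true(all(d$pi[ok] >= 0))
    expect_true(all(d$pi[ok] <=
      (d$n_sequences[ok] / (d$n_sequences[ok] - 1)) * 0.5 + 1e-12))
    expect_true(all((d$pi[ok] == 0) == (d$maf[ok] == 0)))
  }
})

test_that("observed heterozygosity uses the called-genotype denominator", {
  g <- rbind(
    rep(0L, 10),                               # all homozygous
    rep(1L, 10),                               # all heterozygous
    c(rep(1L, 3), rep(0L, 7)),                 # 3/10
    c(rep(1L, 2), rep(2L, 2), rep(-1L, 6))     # 2 het of 4 called
  )
  h <- individual_het(make_panel(g))
  expect_equal(h$ho, c(0, 1, 0.3, 0.5))
  expect_equal(h$n_called, c(10L, 10L, 10L, 4L))
  # all-missing individual is flagged
  h2 <- individual_het(make_panel(rbind(rep(-1L, 3), c(0L, 1L, 2L))))
  expect_true(h2$flagged[1] && is.na(h2$ho[1]))
})

test_that("GRM single-site contributions match the estimator's closed form", {
  # p = 0.5, tested pair both heterozygous: centred genotype is 0
  g1 <- rbind(c(1L), c(1L))
  expect_equal(relatedness_matrix(make_panel(g1))$A[1, 2], 0)

  # p = 0.5 via two hom-ref padding individuals; pair both hom-alt -> 2.0
  g2 <- matrix(c(2L, 2L, 0L, 0L), ncol = 1)
  grm <- relatedness_matrix(make_panel(g2))
  expect_equal(grm$A[1, 2], 2)
  # diagonal for a hom-alt individual at p = 0.5: 1 + (4 - 4 + 0.5)/0.5 = 2
  expect_equal(grm$A[1, 1], 2)
  expect_true(isSymmetric(grm$A))
})

test_that("GRM handles missingness pairwise-complete and permutes consistently", {
  set.seed(31)
  sim <- simulate_panel(sim_config(
    n_individuals = 8,
    chromosomes = data.frame(chrom = "1", length_bp = 2e6, n_snps = 400L),
    missing_rate = 0.1, seed = 31
  ))
  grm <- relatedness_matrix(sim$panel)
  expect_true(isSymmetric(grm$A))
  expect_true(all(is.finite(grm$A)))
  expect_true(all(grm$n_sites <= 400))

  # permuting individuals permutes rows/columns consistently
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  panel2 <- genotype_panel(sim$panel$genotypes[perm, ],
                           sim$panel$sites,
                           sim$panel$individuals[perm])
  grm2 <- relatedness_matrix(panel2)
  expect_equal(grm2$A, grm$A[perm, perm])
})
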