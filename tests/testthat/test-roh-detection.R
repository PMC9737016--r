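test_that("window homozygosity applies the heterozygote and missing budgets", {
  p <- roh_params()
  win <- c(rep(0L, 49), 1L)
  expect_true(window_is_homozygous(win, p))                    # 1 het ok
  expect_false(window_is_homozygous(c(rep(0L, 48), 1L, 1L), p))  # 2 hets
  expect_false(window_is_homozygous(
    c(rep(0L, 43), 1L, rep(-1L, 6)), p))                       # 6 missing
  expect_true(window_is_homozygous(
    c(rep(2L, 44), 1L, rep(-1L, 5)), p))                       # at both budgets
})

test_that("per-SNP flags cover the trivial limit cases", {
  p <- roh_params()
  # fully homozygous chromosome: every window homozygous, every SNP flagged
  expect_true(all(snp_pass_flags(rep(0L, 200), p)))
  # fully heterozygous: no homozygous window anywhere
  expect_true(!any(snp_pass_flags(rep(1L, 200), p)))
  # chromosome shorter than the window: one truncated window decides all
  expect_true(all(snp_pass_flags(rep(2L, 10), p)))
  expect_true(!any(snp_pass_flags(c(rep(1L, 5), rep(0L, 5)), p)))
})

test_that("flag proportions sit at the documented inclusive threshold", {
  # interior SNP of a long chromosome is covered by 50 windows; construct a
  # genotype vector where exactly 3 of them are homozygous: 0.06 >= 0.05
  p <- roh_params()
  codes <- rep(1L, 300)
  codes[120:171] <- 0L  # 3 homozygous windows start at 120,121,122 cover 169
  expect_equal(sum(brute_flags(codes, p)[169]), 1)
  expect_true(snp_pass_flags(codes, p)[169])
  # zero homozygous covering windows -> fail
  expect_false(snp_pass_flags(codes, p)[40])
})

test_that("optimized scan equals the exhaustive window enumeration oracle", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:300, 1)
    params <- roh_params(
      window_size = sample(2:10, 1),
      max_het_in_window = sample(0:2, 1),
      max_missing_in_window = sample(0:2, 1),
      window_pass_threshold = runif(1, 0.01, 0.9),
      edge_mode = sample(c("shrink", "skip"), 1)
    )
    codes <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE,
                    prob = c(0.05, 0.5, 0.25, 0.2))
    expect_identical(snp_pass_flags(codes, params),
                     brute_flags(codes, params))
  }
})

test_that("candidate assembly splits on index breaks and large gaps", {
  p <- roh_params()
  # contiguous flags, small gaps -> one candidate
  r1 <- assemble_candidate_runs(rep(TRUE, 4), c(10, 20, 30, 40) * 1000, p)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_snp, 4L)
  # 150 kb gap between SNPs 2 and 3 -> split into two candidates
  r2 <- assemble_candidate_runs(rep(TRUE, 4), c(10, 20, 170, 180) * 1000, p)
  expect_equal(r2$n_snp, c(2L, 2L))
  # alternating flags -> single-SNP candidates
  r3 <- assemble_candidate_runs(c(TRUE, FALSE, TRUE, FALSE),
                                c(1, 2, 3, 4) * 1000, p)
  expect_equal(r3$n_snp, c(1L, 1L))
})

test_that("run filters enforce SNP count, length and density", {
  p <- roh_params()
  cand <- function(n_snp, length_bp) {
    tibble::tibble(start_pos = 1L, end_pos = as.integer(length_bp),
                   n_snp = n_snp, length_bp = length_bp)
  }
  expect_equal(nrow(filter_runs(cand(120L, 600e3), p)), 1L)  # kept
  expect_equal(nrow(filter_runs(cand(120L, 400e3), p)), 0L)  # too short
  expect_equal(nrow(filter_runs(cand(120L, 6500e3), p)), 0L) # too sparse
  expect_equal(nrow(filter_runs(cand(99L, 600e3), p)), 0L)   # too few SNPs
})

test_that("detect_roh composes the scan on simple whole-chromosome cases", {
  p <- roh_params()
  # fully homozygous 200-SNP chromosome spanning ~1 Mb -> one segment
  pos <- seq(1L, by = 5000L, length.out = 200)
  panel <- make_panel(rbind(rep(0L, 200), rep(1L, 200)), pos = pos)
  roh <- detect_roh(panel, p)
  expect_equal(nrow(roh), 1L)
  expect_equal(roh$individual, "s1")
  expect_equal(roh$n_snp, 200L)
  expect_equal(roh$start_pos, pos[1])
  expect_equal(roh$end_pos, pos[200])
  # all-heterozygous panel -> no segments
  expect_equal(nrow(detect_roh(make_panel(matrix(1L, 2, 300)), p)), 0L)
})

test_that("segment tables satisfy their internal invariants and are deterministic", {
  sim <- simulate_panel(sim_preset_small(seed = 9, n_individuals = 6))
  p <- roh_params()
  roh <- detect_roh(sim$panel, p)
  expect_gt(nrow(roh), 0)
  expect_true(all(roh$start_pos <= roh$end_pos))
  expect_true(all(roh$n_snp >= p$min_snp_in_run))
  expect_true(all(roh$length_bp >= p$min_length_bp))
  expect_true(all(roh$length_bp == roh$end_pos - roh$start_pos + 1))
  expect_true(all(roh$length_bp / roh$n_snp <= p$max_kb_per_snp * 1000))
  # disjoint and sorted within individual x chromosome
  by_ic <- split(roh, paste(roh$individual, roh$chrom))
  expect_true(all(vapply(by_ic, function(s) {
    nrow(s) < 2 || all(diff(s$start_pos) > 0 &
                         s$start_pos[-1] > s$end_pos[-nrow(s)])
  }, logical(1))))
  # byte-identical on re-run
  expect_identical(roh, detect_roh(sim$panel, p))
})

test_that("planted tracts are recovered with boundaries within one SNP interval", {
  # one 1 Mb tract, ~200 SNPs at 5 kb spacing, zero error
  sim <- simulate_panel(sim_config(
    n_individuals = 3,
    chromosomes = data.frame(chrom = "1", length_bp = 10e6, n_snps = 2000L),
    tracts = data.frame(individual = "ind01", chrom = "1",
                        start = 4e6, end = 5e6),
    seed = 12
  ))
  roh <- detect_roh(sim$panel)
  roh1 <- roh[roh$individual == "ind01", ]
  expect_equal(nrow(roh1), 1L)
  spacing <- max(diff(sim$panel$sites$pos))
  expect_lte(abs(roh1$start_pos - 4e6), spacing)
  expect_lte(abs(roh1$end_pos - 5e6), spacing)
})

test_that("relaxing run filters or window budgets is monotone", {
  sim <- simulate_panel(sim_preset_small(seed = 17, n_individuals = 5))
  base <- roh_params()
  n_base <- nrow(detect_roh(sim$panel, base))
  relaxed_len <- roh_params(min_length_bp = 250e3, min_snp_in_run = 50)
  expect_gte(nrow(detect_roh(sim$panel, relaxed_len)), n_base)

  set.seed(41)
  codes <- sample(c(0L, 1L, 2L), 400, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  strict <- roh_params(window_size = 10, max_het_in_window = 0)
  loose <- roh_params(window_size = 10, max_het_in_window = 1)
  expect_true(all(snp_pass_flags(codes, loose) | !snp_pass_flags(codes, strict)))
})
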