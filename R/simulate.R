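#' Simulation configuration for synthetic genotype panels
#'
#' Describes a synthetic diploid SNP panel with the statistical structure
#' the ROH pipeline assumes: background genotypes drawn per site from
#' Hardy-Weinberg proportions at a sampled allele frequency, and planted
#' autozygous tracts (homozygous stretches) with exported ground truth.
#' Sites are simulated independently (no background linkage
#' disequilibrium).
#'
#' Tracts are specified either explicitly via `tracts`, or through a
#' per-individual target autozygosity fraction `f_target`: tract lengths
#' are then drawn from the Mb-class mixture `tract_classes` until the
#' per-individual total matches the target exactly (the last tract is
#' clipped, or its remainder folded into the first tract when it would fall
#' below the smallest class). Tracts of one individual are placed uniformly
#' with a 500 kb minimum separation so that distinct tracts remain distinct
#' runs.
#'
#' @param n_individuals number of diploid individuals.
#' @param chromosomes data frame with `chrom`, `length_bp`, `n_snps`;
#'   default a synthetic 29-autosome genome with linearly declining lengths
#'   (158 to 51 Mb, cattle-like scale) and 1 SNP / 3 kb.
#' @param maf_range range of the uniform minor-allele-frequency
#'   distribution; the alternate allele takes the minor or major role with
#'   equal probability.
#' @param f_target `NULL`, a scalar, or a per-individual vector of target
#'   autozygosity fractions (planted tract bp / genome bp).
#' @param tracts explicit tract table (`individual`, `chrom`, `start`,
#'   `end`) overriding `f_target`.
#' @param tract_classes data frame with `min_mb`, `max_mb`, `weight` giving
#'   the tract-length mixture; default mirrors the empirical ROH length-class
#'   proportions of livestock resequencing panels (0.5-1 Mb dominant).
#' @param het_error_in_tract probability that a tract SNP is rendered
#'   heterozygous (genotyping error).
#' @param missing_rate per-genotype missing probability, applied last.
#' @param seed integer seed; required, all randomness flows from it.
#' @return a list of class `sim_config`.
#' @seealso [simulate_panel()], [sim_preset_small()]
#' @export
sim_config <- function(n_individuals = 30,
                       chromosomes = default_chromosomes(),
                       maf_range = c(0.05, 0.5),
                       f_target = NULL,
                       tracts = NULL,
                       tract_classes = default_tract_classes(),
                       het_error_in_tract = 0,
                       missing_rate = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  chromosomes <- as_tibble(chromosomes)
  stopifnot(
    all(c("chrom", "length_bp", "n_snps") %in% names(chromosomes)),
    all(chromosomes$length_bp > 0), all(chromosomes$n_snps >= 1),
    n_individuals >= 1,
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    het_error_in_tract >= 0, het_error_in_tract <= 1,
    missing_rate >= 0, missing_rate <= 1
  )
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (!is.null(f_target)) {
    f_target <- rep_len(f_target, n_individuals)
    stopifnot(all(f_target >= 0), all(f_target < 1))
  }
  if (!is.null(tracts)) {
    tracts <- as_tibble(tracts)
    stopifnot(all(c("individual", "chrom", "start", "end") %in% names(tracts)))
    chk <- left_join(tracts, chromosomes, by = "chrom")
    if (anyNA(chk$length_bp) || any(tracts$start < 1) ||
        any(chk$end > chk$length_bp)) {
      abort("tract outside chromosome bounds")
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      chromosomes = chromosomes,
      maf_range = maf_range,
      f_target = f_target,
      tracts = tracts,
      tract_classes = as_tibble(tract_classes),
      het_error_in_tract = het_error_in_tract,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Synthetic 29-autosome genome
#'
#' A synthetic stand-in for a bovine-scale autosome set: 29 chromosomes
#' with linearly declining lengths from 158 Mb to 51 Mb (about 2.5 Gb
#' total) and uniform SNP density.
#'
#' @param snp_per_bp SNP density (default 1 per 3 kb).
#' @return a tibble with `chrom`, `length_bp`, `n_snps`.
#' @export
default_chromosomes <- function(snp_per_bp = 1 / 3000) {
  len <- round(seq(158e6, 51e6, length.out = 29))
  tibble(
    chrom = as.character(1:29),
    length_bp = len,
    n_snps = as.integer(round(len * snp_per_bp))
  )
}

#' Default tract-length mixture
#'
#' Mb classes and weights for planted autozygous tracts, dominated by short
#' (0.5-1 Mb) tracts as observed in low-inbreeding resequencing panels.
#'
#' @return a tibble with `min_mb`, `max_mb`, `weight`.
#' @export
default_tract_classes <- function() {
  tibble(
    min_mb = c(0.5, 1, 2, 5),
    max_mb = c(1, 2, 5, 8),
    weight = c(0.737, 0.222, 0.040, 0.001)
  )
}

#' Small simulation preset for fast end-to-end validation
#'
#' 10 individuals, 2 chromosomes of 50 Mb with 10,000 SNPs each (5 kb mean
#' spacing), per-individual autozygosity targets spread evenly over
#' 0.02-0.16 (the range reported for individual F_ROH in low-inbreeding
#' cattle panels), tracts of 1-5 Mb, zero genotyping error and zero
#' missingness. Runs through the whole pipeline in seconds.
#'
#' @param seed integer seed.
#' @param n_individuals number of individuals (targets are re-spread).
#' @return a [sim_config()].
#' @export
sim_preset_small <- function(seed, n_individuals = 10) {
  sim_config(
    n_individuals = n_individuals,
    chromosomes = tibble(chrom = c("1", "2"), length_bp = 50e6,
                         n_snps = 10000L),
    f_target = seq(0.02, 0.16, length.out = n_individuals),
    tract_classes = tibble(min_mb = c(1, 2), max_mb = c(2, 5),
                           weight = c(0.85, 0.15)),
    het_error_in_tract = 0,
    missing_rate = 0,
    seed = seed
  )
}

# draw tract lengths summing exactly to target_bp from the class mixture
draw_tract_lengths <- function(target_bp, classes) {
  min_len <- min(classes$min_mb) * 1e6
  if (target_bp <= 0) return(numeric(0))
  lens <- numeric(0)
  while (sum(lens) < target_bp) {
    cls <- sample.int(nrow(classes), 1, prob = classes$weight)
    lens <- c(lens, runif(1, classes$min_mb[cls], classes$max_mb[cls]) * 1e6)
  }
  over <- sum(lens) - target_bp
  k <- length(lens)
  lens[k] <- lens[k] - over
  if (k > 1 && lens[k] < min_len) {
    lens[1] <- lens[1] + lens[k]
    lens <- lens[-k]
  }
  round(lens)
}

# place tracts on chromosomes, uniform, non-overlapping with margin
place_tracts <- function(lens, chromosomes, margin = 5e5, max_try = 1000) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric())
  for (len in lens) {
    ok <- FALSE
    for (i in seq_len(max_try)) {
      ci <- sample.int(nrow(chromosomes), 1,
                       prob = chromosomes$length_bp)
      clen <- chromosomes$length_bp[ci]
      if (clen < len) next
      start <- floor(runif(1, 1, clen - len + 1))
      end <- start + len - 1
      same <- placed[placed$chrom == chromosomes$chrom[ci], ]
      if (!nrow(same) ||
          all(start > same$end + margin | end < same$start - margin)) {
        placed <- bind_rows(placed, tibble(chrom = chromosomes$chrom[ci],
                                           start = start, end = end))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place tract without overlap; lower f_target")
  }
  placed
}

#' Simulate a genotype panel with planted autozygous tracts
#'
#' Background genotypes are drawn per site from Hardy-Weinberg proportions
#' at the site's sampled alternate-allele frequency. Inside a planted tract
#' the individual is autozygous: one allele is drawn per site with
#' probability equal to the site frequency and doubled into a homozygote,
#' optionally flipped to a heterozygote with probability
#' `het_error_in_tract`. Missingness is applied last. Output is
#' byte-identical for identical seeds.
#'
#' @param cfg a [sim_config()].
#' @return a list with `panel` (a [genotype_panel()]), `truth` (tibble of
#'   planted tracts: `individual`, `chrom`, `start`, `end`, `length_bp`)
#'   and `genome` (a [genome_spec()]).
#' @examples
#' sim <- simulate_panel(sim_preset_small(seed = 1, n_individuals = 4))
#' sim$panel
#' head(sim$truth)
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_ind <- cfg$n_individuals
  individuals <- sprintf("ind%02d", seq_len(n_ind))

  # sites: uniform unique positions, sorted, per chromosome
  sites <- purrr::pmap(cfg$chromosomes, function(chrom, length_bp, n_snps) {
    tibble(
      chrom = chrom,
      pos = sort(sample.int(length_bp, n_snps))
    )
  }) |> bind_rows()
  n_site <- nrow(sites)
  maf <- runif(n_site, cfg$maf_range[1], cfg$maf_range[2])
  flip <- runif(n_site) < 0.5
  p_alt <- ifelse(flip, 1 - maf, maf)
  sites$ref <- "A"
  sites$alt <- "G"
  sites$qual <- NA_real_

  # background HWE genotypes: binomial(2, p) per individual per site
  g <- matrix(
    rbinom(n_ind * n_site, 2L, rep(p_alt, each = n_ind)),
    nrow = n_ind, ncol = n_site,
    dimnames = list(individuals, NULL)
  )

  # planted tracts
  truth <- if (!is.null(cfg$tracts)) {
    mutate(cfg$tracts, individual = as.character(.data$individual))
  } else if (!is.null(cfg$f_target)) {
    total_bp <- sum(cfg$chromosomes$length_bp)
    purrr::map(seq_len(n_ind), function(j) {
      lens <- draw_tract_lengths(cfg$f_target[j] * total_bp, cfg$tract_classes)
      if (!length(lens)) return(NULL)
      mutate(place_tracts(lens, cfg$chromosomes), individual = individuals[j])
    }) |> bind_rows()
  } else {
    tibble(individual = character(), chrom = character(),
           start = numeric(), end = numeric())
  }

  if (nrow(truth)) {
    site_of <- split(seq_len(n_site), factor(sites$chrom, cfg$chromosomes$chrom))
    for (r in seq_len(nrow(truth))) {
      idx <- site_of[[truth$chrom[r]]]
      pos <- sites$pos[idx]
      sel <- idx[pos >= truth$start[r] & pos <= truth$end[r]]
      if (!length(sel)) next
      allele <- rbinom(length(sel), 1L, p_alt[sel])
      geno <- 2L * allele
      if (cfg$het_error_in_tract > 0) {
        err <- runif(length(sel)) < cfg$het_error_in_tract
        geno[err] <- 1L
      }
      g[match(truth$individual[r], individuals), sel] <- geno
    }
    truth <- truth |>
      mutate(length_bp = .data$end - .data$start + 1) |>
      arrange(match(.data$individual, individuals),
              match(.data$chrom, cfg$chromosomes$chrom), .data$start)
  } else {
    truth$length_bp <- numeric(0)
  }

  if (cfg$missing_rate > 0) {
    g[runif(length(g)) < cfg$missing_rate] <- -1L
  }

  list(
    panel = genotype_panel(g, sites, individuals),
    truth = truth,
    genome = genome_spec(cfg$chromosomes$chrom, cfg$chromosomes$length_bp)
  )
}

# total overlap in bp between two sets of disjoint [start,end] intervals
interval_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  if (!length(a_start) || !length(b_start)) return(0)
  total <- 0
  for (i in seq_along(a_start)) {
    lo <- pmax(a_start[i], b_start)
    hi <- pmin(a_end[i], b_end)
    total <- total + sum(pmax(0, hi - lo + 1))
  }
  total
}

#' Evaluate ROH recovery against planted truth
#'
#' Compares detected runs of homozygosity with the planted autozygous
#' tracts, per individual and in aggregate, on a base-pair overlap basis.
#' Recall is the fraction of planted tract bp covered by detected runs;
#' precision the fraction of detected run bp lying inside planted tracts
#' (`NA`, flagged, for individuals with no detections). Boundary errors are
#' the distances between planted and detected endpoints for each tract's
#' best-overlapping run.
#'
#' @param truth planted-tract tibble from [simulate_panel()].
#' @param detected segments tibble from [detect_roh()].
#' @return a list of class `recovery_report`: `per_individual` (tibble with
#'   `individual`, `truth_bp`, `detected_bp`, `overlap_bp`, `recall`,
#'   `precision`, `flagged`), `boundary` (tibble with per-tract
#'   `start_error_bp`, `end_error_bp`), and `summary` (one-row tibble of
#'   aggregate means).
#' @export
evaluate_recovery <- function(truth, detected) {
  truth <- as_segment_tbl(truth)
  det <- as_segment_tbl(detected)
  inds <- union(unique(truth$individual), unique(det$individual))
  per <- purrr::map(inds, function(ind) {
    tt <- truth[truth$individual == ind, ]
    dd <- det[det$individual == ind, ]
    ov <- sum(vapply(unique(c(tt$chrom, dd$chrom)), function(ch) {
      t2 <- tt[tt$chrom == ch, ]
      d2 <- dd[dd$chrom == ch, ]
      interval_overlap_bp(t2$start, t2$end, d2$start_pos, d2$end_pos)
    }, numeric(1)))
    tibble(
      individual = ind,
      truth_bp = sum(tt$end - tt$start + 1),
      detected_bp = if (nrow(dd)) sum(dd$end_pos - dd$start_pos + 1) else 0,
      overlap_bp = ov
    )
  }) |> bind_rows()
  per <- per |>
    mutate(
      recall = ifelse(.data$truth_bp > 0, .data$overlap_bp / .data$truth_bp,
                      NA_real_),
      precision = ifelse(.data$detected_bp > 0,
                         .data$overlap_bp / .data$detected_bp, NA_real_),
      flagged = .data$detected_bp == 0 | .data$truth_bp == 0
    )

  boundary <- purrr::map(seq_len(nrow(truth)), function(r) {
    dd <- det[det$individual == truth$individual[r] &
                det$chrom == truth$chrom[r], ]
    if (!nrow(dd)) return(NULL)
    ov <- pmax(0, pmin(dd$end_pos, truth$end[r]) -
                 pmax(dd$start_pos, truth$start[r]) + 1)
    if (max(ov) == 0) return(NULL)
    best <- which.max(ov)
    tibble(
      individual = truth$individual[r], chrom = truth$chrom[r],
      start_error_bp = abs(dd$start_pos[best] - truth$start[r]),
      end_error_bp = abs(dd$end_pos[best] - truth$end[r])
    )
  }) |> bind_rows()

  summary <- tibble(
    mean_recall = mean(per$recall, na.rm = TRUE),
    mean_precision = mean(per$precision, na.rm = TRUE),
    mean_boundary_error_bp = if (nrow(boundary)) {
      mean(c(boundary$start_error_bp, boundary$end_error_bp))
    } else NA_real_
  )
  structure(
    list(per_individual = per, boundary = boundary, summary = summary),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> mean recall %.4f, mean precision %.4f, mean boundary error %.0f bp\n",
    x$summary$mean_recall, x$summary$mean_precision,
    x$summary$mean_boundary_error_bp
  ))
  invisible(x)
}

#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary
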