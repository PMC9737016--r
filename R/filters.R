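#' Site-filter configuration
#'
#' Population-level SNP quality thresholds applied by [apply_site_filters()].
#' Defaults reproduce a standard resequencing QC: MAF strictly above 0.05,
#' missing genotype rate strictly below 0.1, exact-HWE p strictly above
#' 1e-6, site quality at least 20 (only where a quality value is present),
#' and restriction to the 29 bovine autosomes.
#'
#' @param maf_min minimum minor allele frequency (strict `>`).
#' @param max_missing_rate maximum fraction of missing genotypes (strict `<`).
#' @param hwe_p_min minimum HWE p-value (strict `>`).
#' @param autosomes allowed chromosome labels; `NULL` keeps all.
#' @param site_quality_min minimum site quality (`>=`), applied only to sites
#'   whose quality is recorded; `NULL` disables the check.
#' @param hwe_test `"exact"` (Levene conditional test, default) or `"chisq"`.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05,
                          max_missing_rate = 0.1,
                          hwe_p_min = 1e-6,
                          autosomes = as.character(1:29),
                          site_quality_min = 20,
                          hwe_test = c("exact", "chisq")) {
  stopifnot(
    maf_min >= 0, maf_min <= 0.5,
    max_missing_rate >= 0, max_missing_rate <= 1,
    hwe_p_min >= 0, hwe_p_min <= 1,
    is.null(site_quality_min) || site_quality_min >= 0
  )
  structure(
    list(
      maf_min = maf_min,
      max_missing_rate = max_missing_rate,
      hwe_p_min = hwe_p_min,
      autosomes = if (is.null(autosomes)) NULL else as.character(autosomes),
      site_quality_min = site_quality_min,
      hwe_test = match.arg(hwe_test)
    ),
    class = "filter_config"
  )
}

#' Apply population-level site filters to a genotype panel
#'
#' Sites are screened in a fixed order — autosome, site quality, missingness,
#' MAF, HWE — and each removed site is attributed to its first failing
#' criterion, so the report counts reconcile exactly with the input. (Panels
#' are biallelic by construction; non-biallelic records are dropped at VCF
#' ingestion.) All frequency thresholds are strict as documented in
#' [filter_config()]. If every site is removed a warning is raised and an
#' empty panel is returned.
#'
#' @param panel a [genotype_panel()].
#' @param cfg a [filter_config()].
#' @return a list with elements `panel` (the filtered [genotype_panel()]) and
#'   `report` (a tibble of class `filter_report`: one row per criterion plus
#'   input/retained totals in its attributes).
#' @examples
#' sim <- simulate_panel(sim_config(
#'   n_individuals = 10,
#'   chromosomes = data.frame(chrom = "1", length_bp = 1e6, n_snps = 200),
#'   seed = 1
#' ))
#' res <- apply_site_filters(sim$panel, filter_config(autosomes = "1"))
#' res$report
#' @export
apply_site_filters <- function(panel, cfg = filter_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$sites) == 0) abort("panel has no sites")
  g <- panel$genotypes
  n_ind <- nrow(g)

  n_called <- colSums(g != -1L)
  n_het <- colSums(g == 1L)
  n_hom_alt <- colSums(g == 2L)
  n_hom_ref <- n_called - n_het - n_hom_alt
  alt_copies <- n_het + 2L * n_hom_alt
  p_alt <- ifelse(n_called > 0, alt_copies / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  miss_rate <- 1 - n_called / n_ind

  fail <- rep(NA_character_, ncol(g))
  first_fail <- function(fail, cond, label) {
    ifelse(is.na(fail) & cond, label, fail)
  }
  if (!is.null(cfg$autosomes)) {
    fail <- first_fail(fail, !panel$sites$chrom %in% cfg$autosomes, "non_autosome")
  }
  if (!is.null(cfg$site_quality_min)) {
    fail <- first_fail(
      fail, !is.na(panel$sites$qual) & panel$sites$qual < cfg$site_quality_min,
      "quality"
    )
  }
  fail <- first_fail(fail, !(miss_rate < cfg$max_missing_rate), "missingness")
  fail <- first_fail(fail, is.na(maf) | !(maf > cfg$maf_min), "maf")

  # HWE only computed for sites still alive (it is the last, costliest check)
  alive <- which(is.na(fail))
  if (length(alive)) {
    p_hwe <- if (cfg$hwe_test == "exact") {
      hwe_exact_test(n_hom_ref[alive], n_het[alive], n_hom_alt[alive])
    } else {
      hwe_chisq_test(n_hom_ref[alive], n_het[alive], n_hom_alt[alive])
    }
    fail[alive][!(p_hwe > cfg$hwe_p_min)] <- "hwe"
  }

  keep <- is.na(fail)
  crit <- c("non_biallelic", "non_autosome", "quality", "missingness", "maf", "hwe")
  report <- tibble(
    criterion = crit,
    n_removed = vapply(crit, function(k) sum(fail == k, na.rm = TRUE),
                       integer(1), USE.NAMES = FALSE)
  )
  attr(report, "n_input_sites") <- ncol(g)
  attr(report, "n_retained") <- sum(keep)
  class(report) <- c("filter_report", class(report))

  if (!any(keep)) warn("all sites removed by filters; returning empty panel")
  list(panel = subset_sites(panel, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d sites in, %d retained\n",
              attr(x, "n_input_sites"), attr(x, "n_retained")))
  NextMethod()
}

#' Write a filter report as TSV
#'
#' @param report the `report` element returned by [apply_site_filters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  out <- bind_rows(
    tibble(criterion = "input", n_removed = NA_integer_,
           n_sites = attr(report, "n_input_sites")),
    mutate(as_tibble(report), n_sites = NA_integer_),
    tibble(criterion = "retained", n_removed = NA_integer_,
           n_sites = attr(report, "n_retained"))
  )
  readr::write_tsv(out, path)
  invisible(path)
}
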