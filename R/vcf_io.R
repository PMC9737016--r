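#' Read a multi-sample VCF into a genotype panel
#'
#' Ingests a VCF (plain or gzipped) and keeps only biallelic SNP records on
#' the allowed chromosomes. Genotypes are taken from the GT field; phased
#' (`0|1`) and unphased (`0/1`) calls are treated identically, and any call
#' containing `.` becomes missing. Chromosome labels are normalised by
#' stripping a leading `"chr"` prefix. Sites are sorted by (chromosome,
#' position), chromosomes in numeric-aware order.
#'
#' @param path path to a VCF file (`.vcf` or `.vcf.gz`) with a GT FORMAT
#'   field for every sample.
#' @param autosomes character vector of allowed chromosome labels (after
#'   `"chr"`-stripping); default the bovine autosomes `"1"`–`"29"`. Use
#'   `NULL` to keep every chromosome.
#' @return a [genotype_panel()].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "rohscan")
#' read_vcf(vcf)
#' @export
read_vcf <- function(path, autosomes = as.character(1:29)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) abort(sprintf("VCF has no sample columns: %s", path))
  fmt <- v@gt[, 1]
  if (nrow(v@fix) > 0 && !all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("every VCF record must carry a GT FORMAT field")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  chrom <- normalise_chrom(fix$CHROM)
  alt <- fix$ALT %||% rep(NA_character_, nrow(fix))
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(alt) == 1L & alt != "." & alt != fix$REF
  on_autosome <- if (is.null(autosomes)) rep(TRUE, length(chrom)) else chrom %in% autosomes
  keep <- which(biallelic & on_autosome)

  pos <- as.integer(fix$POS[keep])
  chrom <- chrom[keep]
  qual <- suppressWarnings(as.numeric(fix$QUAL[keep]))
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    abort(sprintf(
      "duplicate site(s) in VCF: %s",
      paste(unique(paste0(chrom[dup], ":", pos[dup])), collapse = ", ")
    ))
  }
  ord <- order(match(chrom, chrom_levels(chrom)), pos)

  gt <- vcfR::extract.gt(v, element = "GT")  # sites x samples
  gt <- gt[keep, , drop = FALSE][ord, , drop = FALSE]
  codes <- gt_to_code(gt)

  genotype_panel(
    t(codes),
    tibble(
      chrom = chrom[ord], pos = pos[ord],
      ref = fix$REF[keep][ord], alt = alt[keep][ord], qual = qual[ord]
    ),
    individuals = colnames(v@gt)[-1]
  )
}

# map GT strings to codes {-1,0,1,2}; anything containing "." is missing
gt_to_code <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(-1L, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[g %in% "0/0"] <- 0L
  code[g %in% c("0/1", "1/0")] <- 1L
  code[g %in% "1/1"] <- 2L
  unknown <- !is.na(g) & !grepl(".", g, fixed = TRUE) &
    !g %in% c("0/0", "0/1", "1/0", "1/1")
  if (any(unknown)) {
    abort(sprintf("unsupported GT value(s): %s",
                  paste(unique(g[unknown]), collapse = ", ")))
  }
  code
}

#' Write a genotype panel as VCF
#'
#' Emits a minimal VCF v4.2 with GT genotypes. The writer round-trips with
#' [read_vcf()]: chromosome, position, alleles, site quality and genotype
#' codes are reproduced exactly. Missing genotypes (`-1`) are written as
#' `./.`.
#'
#' @param panel a [genotype_panel()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$sites
  code_str <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(code_str[as.character(panel$genotypes)],
               nrow = length(panel$individuals))
  qual <- ifelse(is.na(s$qual), ".", formatC(s$qual, format = "g", digits = 15))
  body <- paste(
    s$chrom, s$pos, ".", s$ref, s$alt, qual, "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals), collapse = "\t")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
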