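write_lines_to <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

test_that("BED intervals convert from 0-based half-open to 1-based inclusive", {
  path <- write_lines_to(c("1\t999\t2000\tGENE1", "2\t0\t100\tGENE2"),
                         "genes.bed")
  g <- load_gene_intervals(path)
  expect_equal(g$start, c(1000L, 1L))
  expect_equal(g$end, c(2000L, 100L))
  expect_equal(g$gene_id, c("GENE1", "GENE2"))
})

test_that("GFF3 loading keeps gene records only and round-trips coordinates", {
  gff <- c(
    "##gff-version 3",
    "1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene:G1;Name=CORIN;biotype=protein_coding",
    "1\tsrc\texon\t1000\t1200\t.\t+\t.\tID=exon:E1;Parent=gene:G1",
    "2\tsrc\tgene\t500\t800\t.\t-\t.\tID=gene:G2;Name=SPAST;biotype=protein_coding"
  )
  g <- load_gene_intervals(write_lines_to(gff, "genes.gff3"))
  expect_equal(nrow(g), 2L)
  expect_equal(g$start, c(1000L, 500L))
  expect_equal(g$end, c(2000L, 800L))
  expect_equal(g$gene_name, c("CORIN", "SPAST"))
  expect_equal(g$biotype, c("protein_coding", "protein_coding"))

  # a file with only exon records yields an empty list with a warning
  exons <- c("##gff-version 3",
             "1\tsrc\texon\t10\t20\t.\t+\t.\tID=exon:E1")
  expect_warning(g2 <- load_gene_intervals(write_lines_to(exons, "exons.gff3")),
                 "gene")
  expect_equal(nrow(g2), 0L)
})

test_that("gene overlap requires at least 1 bp on inclusive coordinates", {
  islands <- tibble::tibble(chrom = "1", start_pos = 100L, end_pos = 200L,
                            n_snp = 10L, length_kb = 0, peak_incidence = 0.5)
  genes <- tibble::tibble(
    chrom = "1", start = c(150L, 201L, 200L), end = c(300L, 300L, 250L),
    gene_id = c("G1", "G2", "G3"), gene_name = c("G1", "G2", "G3"),
    biotype = "protein_coding"
  )
  ov <- overlap_genes(islands, genes)
  # G1 overlaps, G3 touches the boundary base 200, G2 starts one bp beyond
  expect_setequal(ov$gene_id, c("G1", "G3"))
})

test_that("overlap join equals the brute-force all-pairs oracle", {
  set.seed(77)
  for (i in 1:10) {
    islands <- tibble::tibble(
      chrom = sample(c("1", "2"), 8, replace = TRUE),
      start_pos = sample.int(1e5, 8)
    ) |>
      dplyr::mutate(end_pos = start_pos + sample.int(2e4, 8),
                    n_snp = 5L, length_kb = 1, peak_incidence = 0.4)
    genes <- tibble::tibble(
      chrom = sample(c("1", "2"), 12, replace = TRUE),
      start = sample.int(1e5, 12)
    ) |>
      dplyr::mutate(end = start + sample.int(5e3, 12),
                    gene_id = paste0("G", 1:12), gene_name = gene_id,
                    biotype = "protein_coding")
    ov <- overlap_genes(islands, genes)
    oracle <- brute_overlap(islands, genes)
    got <- paste(ov$chrom, ov$start_pos, ov$gene_id)
    want <- paste(islands$chrom[oracle[, 1]], islands$start_pos[oracle[, 1]],
                  genes$gene_id[oracle[, 2]])
    expect_setequal(got, want)
  }
})

test_that("annotating a region with six contained genes reports all six", {
  # synthetic fixture shaped like a ~500 kb significant region holding 6 genes
  island <- tibble::tibble(chrom = "11", start_pos = 14444882L,
                           end_pos = 14944596L, n_snp = 89L,
                           length_kb = 500, peak_incidence = 0.4)
  starts <- seq(14500000L, 14900000L, length.out = 6)
  genes <- tibble::tibble(
    chrom = "11", start = as.integer(starts), end = as.integer(starts + 30000),
    gene_id = paste0("G", 1:6),
    gene_name = c("MEMO1", "DPY30", "SPAST", "SLC30A6", "NLRC4", "YIPF4"),
    biotype = "protein_coding"
  )
  ann <- annotate_islands(island, genes)
  expect_equal(ann$n_genes, 6L)
  expect_true(grepl("SPAST", ann$candidate_genes))
  # an island with no overlapping gene reports "None"
  far <- dplyr::mutate(island, chrom = "20")
  expect_equal(annotate_islands(far, genes)$candidate_genes, "None")
})
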