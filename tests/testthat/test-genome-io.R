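test_that("BED6 gene models round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10000\t20000\tGeneA\t0\t+",
               "chr1\t30000\t40000\tGeneB\t0\t-"), path)
  genes <- read_gene_models(path)
  expect_equal(genes$gene_id, c("GeneA", "GeneB"))
  expect_equal(genes$start, c(10000L, 30000L))
  expect_equal(genes$strand, c("+", "-"))

  out <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(genes, out)
  expect_equal(read_gene_models(out), genes)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_gene_models(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tG\t0\t+", "chr2\t0\t10\tG\t0\t+"), dup)
  expect_error(read_gene_models(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tG\t0\t+", "chr1\t5"), bad)
  expect_error(read_gene_models(bad), "line 2")

  inv <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t10\tG\t0\t+", inv)
  expect_error(read_gene_models(inv), "start < end")
})

test_that("region assignment follows promoter > genebody precedence and strand", {
  genes <- tibble::tibble(
    gene_id = c("GeneA", "GeneB"),
    chrom = "chr1",
    start = c(10000L, 30000L),
    end = c(20000L, 40000L),
    strand = c("+", "-")
  )
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(7500L, 12000L, 41000L, 9900L, 50000L),
    end = c(8000L, 12500L, 41200L, 10100L, 50100L),
    score = 2
  )
  res <- assign_region(peaks, genes)
  # + strand: promoter window is [7000, 10000)
  expect_equal(as.character(res$category),
               c("promoter", "genebody", "promoter", "promoter", "intergenic"))
  expect_equal(res$gene_id, c("GeneA", "GeneA", "GeneB", "GeneA", NA))
  # category counts cover all peaks exactly once
  expect_equal(sum(region_distribution(res)$n), nrow(peaks))
  expect_equal(sum(region_distribution(res)$fraction), 1)
})

test_that("unknown chromosomes downgrade to intergenic with a warning", {
  genes <- tibble::tibble(gene_id = "G", chrom = "chr1",
                          start = 0L, end = 100L, strand = "+")
  peaks <- tibble::tibble(chrom = "chrUn", start = 10L, end = 20L, score = 1)
  expect_warning(res <- assign_region(peaks, genes), "intergenic")
  expect_equal(as.character(res$category), "intergenic")
  expect_true(is.na(res$gene_id))
})

test_that("ties across genes break by TSS distance then gene_id", {
  genes <- tibble::tibble(
    gene_id = c("B_far", "A_near"),
    chrom = "chr1",
    start = c(1000L, 2000L),
    end = c(5000L, 6000L),
    strand = "+"
  )
  # peak inside both genebodies, nearer to A_near's TSS
  peak <- tibble::tibble(chrom = "chr1", start = 2100L, end = 2200L, score = 1)
  res <- assign_region(peak, genes, promoter_bp = 10L)
  expect_equal(res$gene_id, "A_near")

  # exact same distance to both TSSs (0 on +, 200 on -) -> lexicographic id
  genes2 <- tibble::tibble(
    gene_id = c("Zed", "Alpha"), chrom = "chr1",
    start = c(0L, 20L), end = c(300L, 200L), strand = c("+", "-")
  )
  peak2 <- tibble::tibble(chrom = "chr1", start = 100L, end = 101L, score = 1)
  res2 <- assign_region(peak2, genes2, promoter_bp = 100L)
  expect_equal(as.character(res2$category), "genebody")
  expect_equal(res2$gene_id, "Alpha")
})

test_that("assignment agrees with the per-base brute-force labeller", {
  chrom_len <- 100000L
  set.seed(42)
  starts <- sort(sample(seq(0L, chrom_len - 6000L, by = 1000L), 12L))
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    chrom = "chrT",
    start = starts,
    end = starts + sample(1000:4000, 12L, replace = TRUE),
    strand = sample(c("+", "-"), 12L, replace = TRUE)
  )
  lab <- oracle_base_labels(genes, chrom_len)
  n <- 1000L
  p_start <- sample.int(chrom_len - 500L, n) - 1L
  peaks <- tibble::tibble(chrom = "chrT", start = p_start,
                          end = p_start + sample(50:500, n, replace = TRUE),
                          score = 1)
  res <- assign_region(peaks, genes)
  expected <- vapply(seq_len(n), function(i) {
    oracle_assign_category(lab, peaks$start[i], peaks$end[i])
  }, "")
  expect_equal(as.character(res$category), expected)
})

test_that("bedGraph coverage queries and validation behave", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t2.5", "chr1\t200\t300\t1.0"), path)
  cov <- read_bedgraph(path)
  expect_equal(coverage_at(cov, "chr1", 50), 2.5)
  expect_equal(coverage_at(cov, "chr1", c(150, 250, 1000)), c(0, 1, 0))
  expect_equal(coverage_at(cov, "chrX", 50), 0)
  expect_equal(coverage_window_sum(cov, "chr1", 0, 300), 250 + 100)
  expect_equal(coverage_window_sum(cov, "chr1", 50, 250), 125 + 50)

  bad <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t2.5", "chr1\t50\t150\t1.0"), bad)
  expect_error(read_bedgraph(bad), "overlapping")
})

test_that("signal matrices round-trip at full precision", {
  sheet <- toy_sheet()
  m <- tibble::tibble(gene_id = c("g1", "g2"),
                      D0 = c(0.123456789012345, 2),
                      D3 = c(1 / 3, 7.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path, sheet)
  expect_equal(back, m, tolerance = 0)
  expect_identical(back$D3[1], m$D3[1])

  # unknown label rejected against the sheet
  m2 <- dplyr::rename(m, nope = "D3")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m2, path2)
  expect_error(read_matrix(path2, sheet), "absent from sample sheet")

  # single gene, many samples: column order preserved
  wide <- toy_matrix(list(g1 = 1:7))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(wide, path3)
  expect_equal(names(read_matrix(path3)), names(wide))

  # non-numeric cell rejected
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tD0", "g1\tabc"), path4)
  expect_error(suppressWarnings(read_matrix(path4)))
})

test_that("presence matrices serialise as 0/1 and read back as logical", {
  p <- tibble::tibble(gene_id = c("a", "b"), D0 = c(TRUE, FALSE),
                      D3 = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(p, path)
  expect_match(readLines(path)[2], "^a\t1\t0$")
  expect_equal(read_presence_matrix(path), p)
})
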