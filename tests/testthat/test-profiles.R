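random_coverage <- function(chrom = "chr1", n = 30L, span = 100000L) {
  edges <- sort(sample.int(span, 2L * n))
  tibble::tibble(
    chrom = chrom,
    start = edges[seq(1L, 2L * n, by = 2L)] - 1L,
    end = edges[seq(2L, 2L * n, by = 2L)],
    value = round(runif(n, 0, 5), 3)
  )
}

test_that("profiles are flat on uniform coverage and empty on none", {
  cov <- stepwise_coverage(tibble::tibble(chrom = "chr1", start = 0,
                                          end = 1e6, value = 1))
  anchors <- tibble::tibble(chrom = "chr1",
                            position = c(5000, 20000, 77000),
                            strand = c("+", "-", "+"))
  prof <- bin_signal(cov, anchors, flank = 1000, n_bins = 20)
  expect_equal(prof$mean_signal, rep(1, 20))

  empty <- stepwise_coverage(tibble::tibble(chrom = "chr1", start = 0,
                                            end = 10, value = 0))
  prof0 <- bin_signal(empty, anchors, flank = 1000, n_bins = 20)
  expect_equal(prof0$mean_signal, rep(0, 20))
})

test_that("a 1-bp spike lands in exactly one bin and conserves mass", {
  cov <- stepwise_coverage(tibble::tibble(chrom = "chr1", start = 10350,
                                          end = 10351, value = 7))
  anchors <- tibble::tibble(chrom = "chr1", position = 10000, strand = "+")
  prof <- bin_signal(cov, anchors, flank = 1000, n_bins = 20)
  expect_equal(sum(prof$mean_signal > 0), 1L)
  # spike at +350 -> bin 14 (bins of 100 bp starting at -1000)
  expect_equal(which(prof$mean_signal > 0), 14L)
  expect_equal(sum(prof$mean_signal) * 100, 7)

  # minus-strand anchor mirrors the bin index
  anchors_m <- tibble::tibble(chrom = "chr1", position = 10000, strand = "-")
  prof_m <- bin_signal(cov, anchors_m, flank = 1000, n_bins = 20)
  expect_equal(which(prof_m$mean_signal > 0), 7L)
})

test_that("binned profiles conserve total per-base signal against brute force", {
  set.seed(101)
  for (rep in 1:100) {
    tbl <- random_coverage()
    cov <- stepwise_coverage(tbl)
    anchors <- tibble::tibble(
      chrom = "chr1",
      position = sample(2000:98000, 5L),
      strand = sample(c("+", "-"), 5L, replace = TRUE)
    )
    flank <- sample(c(500L, 1000L, 2000L), 1L)
    n_bins <- sample(c(10L, 20L, 40L), 1L)
    prof <- bin_signal(cov, anchors, flank, n_bins)
    width <- 2 * flank / n_bins
    binned_mass <- sum(prof$mean_signal) * width * nrow(anchors)
    # brute force: evaluate coverage at every base in every window
    brute <- sum(vapply(seq_len(nrow(anchors)), function(i) {
      win <- (anchors$position[i] - flank):(anchors$position[i] + flank - 1L)
      sum(coverage_at(cov, "chr1", win))
    }, 0))
    expect_equal(binned_mass, brute, tolerance = 1e-9)
  }
})

test_that("strand symmetry: mirrored coverage with flipped strands is invariant", {
  set.seed(5)
  tbl <- random_coverage(span = 50000L)
  cov <- stepwise_coverage(tbl)
  anchors <- tibble::tibble(chrom = "chr1", position = c(10000, 30000),
                            strand = c("+", "-"))
  prof <- bin_signal(cov, anchors, flank = 1000, n_bins = 10)

  # mirror the genome around M so base x maps to 2M - 1 - x
  m <- 50000
  mirrored <- tibble::tibble(chrom = "chr1", start = 2 * m - tbl$end,
                             end = 2 * m - tbl$start, value = tbl$value)
  cov_m <- stepwise_coverage(mirrored)
  anchors_m <- tibble::tibble(chrom = "chr1",
                              position = 2 * m - anchors$position,
                              strand = c("-", "+"))
  prof_m <- bin_signal(cov_m, anchors_m, flank = 1000, n_bins = 10)
  expect_equal(prof_m$mean_signal, prof$mean_signal, tolerance = 1e-12)
})

test_that("windows reaching past coordinate 0 are clamped with a warning", {
  cov <- stepwise_coverage(tibble::tibble(chrom = "chr1", start = 0,
                                          end = 1000, value = 2))
  anchors <- tibble::tibble(chrom = "chr1", position = 100, strand = "+")
  expect_warning(prof <- bin_signal(cov, anchors, flank = 500, n_bins = 10),
                 "clamped")
  expect_equal(attr(prof, "n_clamped"), 1L)
  # covered bins still average correctly
  expect_equal(prof$mean_signal[5:10], rep(2, 6))
})

test_that("metagene genebody profile averages per-bp signal 5' to 3'", {
  # gene on - strand: high signal at its 3' half in genome coordinates
  cov <- stepwise_coverage(tibble::tibble(chrom = "chr1",
                                          start = c(1000, 1500),
                                          end = c(1500, 2000),
                                          value = c(4, 0)))
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1000L,
                          end = 2000L, strand = "-")
  prof <- bin_genebody(cov, genes, n_bins = 10)
  # 5' end of the minus-strand gene is at coordinate 2000 (value 0)
  expect_equal(prof$mean_signal, c(rep(0, 5), rep(4, 5)))
})

test_that("gene-set trajectories are means with standard errors along the route", {
  sheet <- toy_sheet()
  m <- toy_matrix(list(g1 = c(1, 3, 5, 7, 9, 11, 13),
                       g2 = c(3, 5, 7, 9, 11, 13, 15)))
  traj <- geneset_trajectory(m, sheet, c("g1", "g2"), "successful")
  expect_equal(traj$mean, c(2, 4, 6, 8, 10, 12, 14))
  expect_equal(traj$sample_label, route_labels(sheet, "successful"))
  expect_equal(traj$se, rep(stats::sd(c(1, 3)) / sqrt(2), 7))

  single <- geneset_trajectory(m, sheet, "g1", "successful")
  expect_equal(single$mean, c(1, 3, 5, 7, 9, 11, 13))

  expect_error(geneset_trajectory(m, sheet, character()), "non-empty")
  expect_error(geneset_trajectory(m, sheet, "nope"), "absent")
})

test_that("planted fibroblast trajectory decreases along the successful route", {
  cfg <- zero_noise_config(seed = 21L, n_genes = 200L)
  sim <- simulate_matrices(cfg)
  ip <- normalize_library(sim$h33_ip, sim$library_sizes)
  fib <- sim$truth$gene_id[sim$truth$class == "fibroblast"]
  traj <- geneset_trajectory(ip, sim$sheet, fib, "successful",
                             geneset_name = "fibroblast")
  expect_true(all(diff(traj$mean) < 0))
  # direct recomputation
  labels <- route_labels(sim$sheet, "successful")
  manual <- colMeans(as.matrix(ip[ip$gene_id %in% fib, labels]))
  expect_equal(traj$mean, unname(manual))
})

test_that("trajectory and profile plots build", {
  sheet <- toy_sheet()
  m <- toy_matrix(list(g1 = 7:1, g2 = c(3, 5, 7, 9, 11, 13, 15)))
  traj <- geneset_trajectory(m, sheet, c("g1", "g2"), "successful")
  expect_s3_class(ggplot2::autoplot(traj), "ggplot")
  cov <- stepwise_coverage(tibble::tibble(chrom = "chr1", start = 0,
                                          end = 1e4, value = 1))
  prof <- bin_signal(cov, tibble::tibble(chrom = "chr1", position = 5000,
                                         strand = "+"), 1000, 10)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})
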