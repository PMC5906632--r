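#' Binned average-enrichment profile around anchors
#'
#' For each anchor the window `[position - flank, position + flank)` is split
#' into `n_bins` equal bins; windows of minus-strand anchors are reversed so
#' that bins run 5' to 3'.  The profile value of a bin is the mean per-base
#' signal over all anchors, computed exactly on stepwise coverage, so total
#' signal is conserved: `sum(mean_signal * bin width * n_anchors)` equals the
#' per-base sum over all (unclamped) windows.  Windows that would extend past
#' coordinate 0 are clamped and averaged over their covered bases only; the
#' number of clamped anchors is reported via a warning and the `n_clamped`
#' attribute.
#'
#' @param cov A `stepwise_coverage` object (see [read_bedgraph()]).
#' @param anchors Tibble with columns `chrom`, `position`, `strand`.
#' @param flank Half-window width in bp (> 0).
#' @param n_bins Number of bins; `2 * flank` must be divisible by `n_bins`.
#' @return A tibble of class `h33_profile` with columns `bin` (1-based),
#'   `bin_center` (bp offset of the bin centre from the anchor, 5'->3'),
#'   `mean_signal` and attribute `n_anchors`.
#' @export
bin_signal <- function(cov, anchors, flank, n_bins) {
  if (flank <= 0) rlang::abort("flank must be > 0")
  if (n_bins < 1L) rlang::abort("n_bins must be >= 1")
  if ((2 * flank) %% n_bins != 0) {
    rlang::abort("2 * flank must be divisible by n_bins")
  }
  width <- 2 * flank / n_bins
  sums <- numeric(n_bins)
  bases <- numeric(n_bins)
  n_clamped <- 0L
  for (i in seq_len(nrow(anchors))) {
    pos <- anchors$position[i]
    edges <- pos - flank + width * (0:n_bins)
    lo <- pmax(edges[-(n_bins + 1L)], 0)
    hi <- pmax(edges[-1L], 0)
    if (edges[1L] < 0) n_clamped <- n_clamped + 1L
    covered <- hi - lo
    s <- coverage_window_sum(cov, anchors$chrom[i], lo, hi)
    if (identical(anchors$strand[i], "-")) {
      s <- rev(s)
      covered <- rev(covered)
    }
    sums <- sums + s
    bases <- bases + covered
  }
  if (n_clamped > 0L) {
    rlang::warn(paste0(n_clamped, " anchor window(s) clamped at coordinate 0"))
  }
  mean_signal <- ifelse(bases > 0, sums / bases, 0)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center = -flank + width * (seq_len(n_bins) - 0.5),
    mean_signal = mean_signal
  )
  structure(out, class = c("h33_profile", class(out)),
            n_anchors = nrow(anchors), bin_width = width,
            n_clamped = n_clamped)
}

#' Metagene profile over scaled genebodies
#'
#' Each gene interval is scaled to `n_bins` bins of (near-)equal width and the
#' per-base mean signal of each bin is averaged over genes, minus-strand genes
#' reversed.  This is the fixed-bin metagene convention of average-profile
#' tools.
#'
#' @param cov A `stepwise_coverage` object.
#' @param genes Gene-catalog tibble.
#' @param n_bins Number of genebody bins (default 100).
#' @return A `h33_profile` tibble with `bin`, `bin_center` (fraction of the
#'   genebody, 0 to 1) and `mean_signal`.
#' @export
bin_genebody <- function(cov, genes, n_bins = 100L) {
  validate_gene_models(genes)
  sums <- numeric(n_bins)
  bases <- numeric(n_bins)
  for (i in seq_len(nrow(genes))) {
    edges <- round(seq(genes$start[i], genes$end[i], length.out = n_bins + 1L))
    lo <- edges[-(n_bins + 1L)]
    hi <- edges[-1L]
    s <- coverage_window_sum(cov, genes$chrom[i], lo, hi)
    covered <- hi - lo
    if (genes$strand[i] == "-") {
      s <- rev(s)
      covered <- rev(covered)
    }
    sums <- sums + s
    bases <- bases + covered
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center = (seq_len(n_bins) - 0.5) / n_bins,
    mean_signal = ifelse(bases > 0, sums / bases, 0)
  )
  structure(out, class = c("h33_profile", class(out)),
            n_anchors = nrow(genes))
}

#' Gene-set trajectory along a route
#'
#' Per time-point arithmetic mean and standard error of a signal matrix over
#' a gene set, with samples ordered along the chosen route (shared samples
#' included).  This reproduces line plots of, e.g., mean normalised H3.3
#' genebody signal over a fibroblast or pluripotency gene set.
#'
#' @param matrix Signal-matrix tibble.
#' @param sheet Sample-sheet tibble.
#' @param geneset Character vector of gene ids (must all be in the matrix).
#' @param route `"successful"` or `"unsuccessful"`.
#' @param assay Assay whose samples to use (default `"chip_ip"`).
#' @param geneset_name Label carried into the output.
#' @return A tibble of class `h33_trajectory` with columns `sample_label`,
#'   `mean`, `se`, `n_genes`, `geneset_name`.
#' @export
geneset_trajectory <- function(matrix, sheet, geneset,
                               route = c("successful", "unsuccessful"),
                               assay = "chip_ip", geneset_name = "geneset") {
  route <- rlang::arg_match(route)
  validate_signal_matrix(matrix)
  if (length(geneset) == 0L) rlang::abort("geneset must be non-empty")
  missing <- setdiff(geneset, matrix$gene_id)
  if (length(missing) > 0L) {
    rlang::abort(paste0("geneset gene(s) absent from matrix: ",
                        paste(utils::head(missing, 5L), collapse = ", ")))
  }
  labels <- route_labels(sheet, route, assay = assay)
  absent <- setdiff(labels, names(matrix))
  if (length(absent) > 0L) {
    rlang::abort(paste0("matrix missing route sample(s): ",
                        paste(absent, collapse = ", ")))
  }
  v <- sm_values(matrix)[matrix$gene_id %in% geneset, labels, drop = FALSE]
  n <- nrow(v)
  se <- if (n > 1L) apply(v, 2L, stats::sd) / sqrt(n) else rep(0, length(labels))
  out <- tibble::tibble(
    sample_label = labels,
    mean = unname(colMeans(v)),
    se = unname(se),
    n_genes = n,
    geneset_name = geneset_name
  )
  structure(out, class = c("h33_trajectory", class(out)), route = route)
}

#' Plot an average-enrichment profile
#'
#' @param object A `h33_profile` tibble from [bin_signal()] or
#'   [bin_genebody()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.h33_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$mean_signal)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "position relative to anchor",
                  y = "mean signal per bp",
                  title = paste0("average profile (n = ",
                                 attr(object, "n_anchors"), " anchors)")) +
    ggplot2::theme_minimal()
}

#' Plot a gene-set trajectory
#'
#' @param object A `h33_trajectory` tibble from [geneset_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.h33_trajectory <- function(object, ...) {
  object$sample_label <- factor(object$sample_label,
                                levels = object$sample_label)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_label, y = .data$mean,
                                       group = .data$geneset_name)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "mean normalised signal",
                  title = unique(object$geneset_name)) +
    ggplot2::theme_minimal()
}
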