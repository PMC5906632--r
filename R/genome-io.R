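#' Read a gene catalog from BED6
#'
#' Gene models are BED6 records (0-based half-open coordinates): chrom, start,
#' end, gene id, score (ignored), strand.  The transcription start site (TSS)
#' is `start` on the plus strand and `end` on the minus strand; the genebody
#' spans the full interval.
#'
#' @param path Path to a BED6 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed BED6 line ", bad[1L], " in ", path,
                        ": expected >= 6 tab-separated fields"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    rlang::abort(paste0("malformed BED6 line ", bad, " in ", path,
                        ": non-integer coordinates"))
  }
  genes <- tibble::tibble(
    gene_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end,
    strand = vapply(fields, `[[`, "", 6L)
  )
  validate_gene_models(genes)
  genes
}

validate_gene_models <- function(genes) {
  if (any(genes$start < 0L) || any(genes$start >= genes$end)) {
    rlang::abort("gene models require 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    rlang::abort("gene strand must be '+' or '-'")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate gene_id in catalog: ",
                        paste(unique(dup), collapse = ", ")))
  }
  invisible(genes)
}

#' Write gene models to BED6
#'
#' @param genes Gene-catalog tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  bed <- tibble::tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0L, strand = genes$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read and write peak calls (BED)
#'
#' Peaks are BED intervals with an optional score column (column 5,
#' fold-enrichment; missing scores default to 0).  Coordinates are 0-based
#' half-open.
#'
#' @param path File path.
#' @param peaks Tibble with columns `chrom`, `start`, `end`, `score`.
#' @return `read_peaks()` returns a tibble `chrom`, `start`, `end`, `score`.
#' @export
read_peaks <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed BED line ", bad[1L], " in ", path))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end) || any(start < 0L) || any(start >= end)) {
    rlang::abort(paste0("invalid peak coordinates in ", path,
                        " (need 0 <= start < end)"))
  }
  score <- vapply(fields, function(f) {
    if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]])) else 0
  }, 0)
  score[is.na(score)] <- 0
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end, score = score
  )
}

#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  bed <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = paste0("peak_", seq_len(nrow(peaks))), score = peaks$score
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Assign peaks to promoter, genebody or intergenic categories
#'
#' Each peak receives exactly one category.  The promoter window of a gene is
#' the `promoter_bp` bases strictly upstream of its TSS (strand-aware,
#' clamped at coordinate 0); the genebody is the full gene interval.  A peak
#' overlapping any promoter window (by at least one base) is a promoter peak;
#' otherwise a peak overlapping any genebody is a genebody peak; otherwise it
#' is intergenic.  When several genes compete within a category, the tie is
#' broken by smallest distance from the peak to the gene TSS, then by
#' lexicographic `gene_id`.  Peaks on chromosomes absent from the catalog are
#' classified intergenic with a warning.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `score`).
#' @param genes Gene-catalog tibble (see [read_gene_models()]).
#' @param promoter_bp Promoter window width in bp upstream of the TSS
#'   (default 3000).
#' @return The peak tibble with added columns `category` (factor with levels
#'   promoter, genebody, intergenic) and `gene_id` (`NA` for intergenic).
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "GeneA", chrom = "chr1",
#'                         start = 10000L, end = 20000L, strand = "+")
#' peaks <- tibble::tibble(chrom = "chr1", start = 7500L, end = 8000L, score = 2)
#' assign_region(peaks, genes)
assign_region <- function(peaks, genes, promoter_bp = 3000L) {
  if (promoter_bp <= 0L) rlang::abort("promoter_bp must be > 0")
  validate_gene_models(genes)
  categories <- c("promoter", "genebody", "intergenic")
  out <- peaks
  out$.peak_id <- seq_len(nrow(peaks))
  if (nrow(peaks) == 0L) {
    out$category <- factor(character(), levels = categories)
    out$gene_id <- character()
    out$.peak_id <- NULL
    return(tibble::as_tibble(out))
  }

  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, tss = tss,
    w_start = ifelse(genes$strand == "+",
                     pmax(0L, genes$start - promoter_bp), genes$end),
    w_end = ifelse(genes$strand == "+", genes$start,
                   genes$end + promoter_bp),
    category = "promoter"
  )
  body <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, tss = tss,
    w_start = genes$start, w_end = genes$end, category = "genebody"
  )
  windows <- dplyr::bind_rows(prom, body) |>
    dplyr::filter(.data$w_start < .data$w_end) |>
    dplyr::mutate(w_last = .data$w_end - 1L)

  pk <- tibble::tibble(
    .peak_id = out$.peak_id, chrom = peaks$chrom,
    p_start = peaks$start, p_last = peaks$end - 1L
  )
  unknown <- !(peaks$chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    rlang::warn(paste0(sum(unknown),
                       " peak(s) on chromosome(s) absent from the gene catalog;",
                       " classified as intergenic"))
  }

  hits <- dplyr::inner_join(
    pk, windows,
    by = dplyr::join_by("chrom",
                        overlaps(x$p_start, x$p_last, y$w_start, y$w_last)),
    relationship = "many-to-many"
  )
  best <- hits |>
    dplyr::mutate(
      tss_dist = ifelse(.data$tss >= .data$p_start & .data$tss <= .data$p_last,
                        0L,
                        pmin(abs(.data$p_start - .data$tss),
                             abs(.data$p_last - .data$tss))),
      cat_rank = match(.data$category, categories)
    ) |>
    dplyr::arrange(.data$.peak_id, .data$cat_rank, .data$tss_dist,
                   .data$gene_id) |>
    dplyr::distinct(.data$.peak_id, .keep_all = TRUE) |>
    dplyr::select(".peak_id", "category", "gene_id")

  out <- dplyr::left_join(tibble::as_tibble(out), best, by = ".peak_id") |>
    dplyr::mutate(
      category = factor(ifelse(is.na(.data$category), "intergenic",
                               .data$category), levels = categories),
      gene_id = ifelse(.data$category == "intergenic", NA_character_,
                       .data$gene_id)
    ) |>
    dplyr::select(-".peak_id")
  out
}

#' Region category distribution
#'
#' Summarises an annotated peak table into category counts and fractions
#' (which sum to 1 by construction).
#'
#' @param assigned Output of [assign_region()].
#' @return Tibble with `category`, `n`, `fraction`.
#' @export
region_distribution <- function(assigned) {
  assigned |>
    dplyr::count(.data$category, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Read a bedGraph file into stepwise coverage
#'
#' The file must be 4-column bedGraph (chrom, start, end, value; 0-based
#' half-open) with non-overlapping intervals per chromosome.  The returned
#' object evaluates to the listed value inside an interval and 0 elsewhere.
#'
#' @param path Path to a bedGraph file.
#' @return A `stepwise_coverage` object; query it with [coverage_at()] and
#'   [coverage_window_sum()].
#' @export
read_bedgraph <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      value = readr::col_double()
    ),
    comment = "#"
  )
  stepwise_coverage(tbl)
}

#' Construct stepwise coverage from an interval table
#'
#' @param tbl Tibble with columns `chrom`, `start`, `end`, `value`.
#' @return A `stepwise_coverage` object.
#' @export
stepwise_coverage <- function(tbl) {
  if (any(tbl$start < 0) || any(tbl$start >= tbl$end)) {
    rlang::abort("coverage intervals require 0 <= start < end")
  }
  by_chrom <- split(tbl[c("start", "end", "value")], tbl$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1L] < d$end[-nrow(d)])) {
      rlang::abort("overlapping coverage intervals within a chromosome")
    }
    # prefix integral of value over [0, x) for O(log n) window sums
    d$cum <- c(0, cumsum(d$value * (d$end - d$start)))[seq_len(nrow(d))]
    d
  })
  structure(list(chroms = by_chrom), class = "stepwise_coverage")
}

#' @export
print.stepwise_coverage <- function(x, ...) {
  n <- vapply(x$chroms, nrow, 0L)
  cat("<stepwise_coverage>", length(n), "chromosome(s),",
      sum(n), "interval(s)\n")
  invisible(x)
}

# integral of the coverage over [0, pos) for one chromosome
coverage_prefix <- function(cov, chrom, pos) {
  d <- cov$chroms[[chrom]]
  if (is.null(d)) return(numeric(length(pos)))
  i <- findInterval(pos, d$start)
  full <- ifelse(i > 0L, d$cum[pmax(i, 1L)], 0)
  partial <- ifelse(
    i > 0L,
    d$value[pmax(i, 1L)] *
      pmax(0, pmin(pos, d$end[pmax(i, 1L)]) - d$start[pmax(i, 1L)]),
    0
  )
  full + partial
}

#' Query stepwise coverage
#'
#' `coverage_at()` returns the per-base value at positions; 0 outside all
#' intervals.  `coverage_window_sum()` returns the exact sum of per-base
#' values over `[start, end)`.
#'
#' @param cov A `stepwise_coverage` object.
#' @param chrom Chromosome name (length 1).
#' @param pos,start,end Base coordinates (vectors for `pos`; `start`/`end`
#'   may be vectors of equal length).
#' @return Numeric vector.
#' @export
coverage_at <- function(cov, chrom, pos) {
  d <- cov$chroms[[chrom]]
  if (is.null(d)) return(numeric(length(pos)))
  i <- findInterval(pos, d$start)
  inside <- i > 0L & pos < d$end[pmax(i, 1L)]
  out <- numeric(length(pos))
  out[inside] <- d$value[i[inside]]
  out
}

#' @rdname coverage_at
#' @export
coverage_window_sum <- function(cov, chrom, start, end) {
  coverage_prefix(cov, chrom, end) - coverage_prefix(cov, chrom, start)
}

#' Write stepwise coverage as bedGraph
#'
#' @param cov A `stepwise_coverage` object or an interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  tbl <- if (inherits(cov, "stepwise_coverage")) {
    dplyr::bind_rows(lapply(names(cov$chroms), function(ch) {
      d <- cov$chroms[[ch]]
      tibble::tibble(chrom = ch, start = d$start, end = d$end, value = d$value)
    }))
  } else {
    cov[c("chrom", "start", "end", "value")]
  }
  readr::write_tsv(tbl, path, col_names = FALSE)
  invisible(path)
}

#' Read and write gene-by-sample signal matrices
#'
#' Signal matrices (normalised tag counts, FPKM, accessibility) are tibbles
#' whose first column is `gene_id` and whose remaining columns are numeric,
#' one per sample label.  On disk they are TSV with full decimal precision so
#' that a write/read round trip is the identity.
#'
#' @param path File path.
#' @param sheet Optional sample sheet; when given, every sample column must
#'   match a label in the sheet.
#' @param matrix Signal-matrix tibble.
#' @return `read_matrix()` returns a signal-matrix tibble.
#' @export
read_matrix <- function(path, sheet = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), comment = "#")
  if (names(tbl)[1L] != "gene_id") {
    rlang::abort("matrix file must have 'gene_id' as its first column")
  }
  bad <- !vapply(tbl[-1L], is.numeric, TRUE)
  if (any(bad)) {
    rlang::abort(paste0("non-numeric matrix column(s): ",
                        paste(names(tbl[-1L])[bad], collapse = ", ")))
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(names(tbl)[-1L], sheet$label)
    if (length(unknown) > 0L) {
      rlang::abort(paste0("matrix sample label(s) absent from sample sheet: ",
                          paste(unknown, collapse = ", ")))
    }
  }
  validate_signal_matrix(tbl)
  tbl
}

#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path) {
  validate_signal_matrix(matrix)
  readr::write_tsv(matrix, path)
  invisible(path)
}

validate_signal_matrix <- function(matrix, logical_ok = FALSE) {
  if (!is.data.frame(matrix) || names(matrix)[1L] != "gene_id") {
    rlang::abort("a signal matrix must have 'gene_id' as its first column")
  }
  ok <- vapply(matrix[-1L],
               function(x) is.numeric(x) || (logical_ok && is.logical(x)),
               TRUE)
  if (!all(ok)) rlang::abort("signal-matrix sample columns must be numeric")
  vals <- as.matrix(matrix[-1L])
  if (!logical_ok && length(vals) > 0L && any(!is.finite(vals))) {
    rlang::abort("signal-matrix values must all be finite")
  }
  if (anyDuplicated(matrix$gene_id)) {
    rlang::abort("duplicate gene_id in signal matrix")
  }
  invisible(matrix)
}

# numeric matrix view of a signal-matrix tibble, rownames = gene_id
sm_values <- function(matrix) {
  m <- as.matrix(matrix[-1L])
  rownames(m) <- matrix$gene_id
  m
}

# rebuild a signal-matrix tibble from a numeric matrix
sm_rebuild <- function(values, gene_ids = rownames(values)) {
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = gene_ids),
    tibble::as_tibble(values)
  ))
}

#' Read and write boolean presence matrices
#'
#' Presence matrices share the signal-matrix layout but hold logical
#' enrichment calls, serialised as 0/1.
#'
#' @param path File path.
#' @param presence Presence-matrix tibble (logical sample columns).
#' @return `read_presence_matrix()` returns a tibble with logical columns.
#' @export
read_presence_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_integer()
  ), comment = "#")
  dplyr::mutate(tbl, dplyr::across(-"gene_id", as.logical))
}

#' @rdname read_presence_matrix
#' @export
write_presence_matrix <- function(presence, path) {
  validate_signal_matrix(presence, logical_ok = TRUE)
  out <- dplyr::mutate(presence, dplyr::across(-"gene_id", as.integer))
  readr::write_tsv(out, path)
  invisible(path)
}
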