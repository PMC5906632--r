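#' Rank genes by loss of H3.3 signal
#'
#' Scores each gene by the largest drop of normalised genebody signal between
#' consecutive time-points of the successful route (floored at 0), which
#' operationalises "depleted of enrichment at any time-point".  Ties are
#' broken by total loss (sum of all consecutive drops) and then by `gene_id`.
#'
#' @param matrix Normalised signal-matrix tibble.
#' @param sheet Sample-sheet tibble.
#' @param n Number of top genes to return (default 250).
#' @param assay Assay whose successful-route samples to use.
#' @return Tibble `gene_id`, `loss_score`, `total_loss`, `rank`, sorted by
#'   decreasing loss.
#' @export
rank_h33_loss <- function(matrix, sheet, n = 250L, assay = "chip_ip") {
  if (n <= 0L) rlang::abort("n must be > 0")
  validate_signal_matrix(matrix)
  labels <- route_labels(sheet, "successful", assay = assay)
  if (length(labels) < 2L) {
    rlang::abort("need at least two successful-route samples")
  }
  v <- sm_values(matrix)[, labels, drop = FALSE]
  drops <- v[, -ncol(v), drop = FALSE] - v[, -1L, drop = FALSE]
  scored <- tibble::tibble(
    gene_id = matrix$gene_id,
    loss_score = unname(pmax(apply(drops, 1L, max), 0)),
    total_loss = unname(rowSums(pmax(drops, 0)))
  ) |>
    dplyr::arrange(dplyr::desc(.data$loss_score),
                   dplyr::desc(.data$total_loss), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  dplyr::slice_head(scored, n = min(n, nrow(scored)))
}

#' Functional-target intersection (two-set Venn)
#'
#' Intersects a set of genes down-regulated upon H3.3 knockdown with a set of
#' genes losing H3.3 along the successful route, reporting the intersection
#' and the three Venn region sizes.
#'
#' @param down_on_knockdown,losing_h33 Character vectors of gene ids from a
#'   common universe.
#' @param names Length-2 labels for the two sets.
#' @return An object of class `venn_overlap` with elements `targets` (the
#'   sorted intersection), `only_first`, `only_second`; use [tidy()] for the
#'   region-size table.
#' @export
#' @examples
#' functional_targets(c("A", "B", "C"), c("B", "C", "D"))
functional_targets <- function(down_on_knockdown, losing_h33,
                               names = c("down_on_knockdown", "losing_h33")) {
  a <- unique(down_on_knockdown)
  b <- unique(losing_h33)
  structure(
    list(
      targets = sort(intersect(a, b)),
      only_first = sort(setdiff(a, b)),
      only_second = sort(setdiff(b, a)),
      set_names = names
    ),
    class = "venn_overlap"
  )
}

#' @export
print.venn_overlap <- function(x, ...) {
  cat("<venn_overlap>", x$set_names[1L], "vs", x$set_names[2L], "\n")
  cat("  intersection:", length(x$targets),
      "| only first:", length(x$only_first),
      "| only second:", length(x$only_second), "\n")
  invisible(x)
}

#' @rdname functional_targets
#' @param x A `venn_overlap` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.venn_overlap <- function(x, ...) {
  tibble::tibble(
    region = c(paste0("only_", x$set_names[1L]), "intersection",
               paste0("only_", x$set_names[2L])),
    size = c(length(x$only_first), length(x$targets), length(x$only_second))
  )
}

#' Identify route-exclusive H3.3-dependent activators
#'
#' A gene is called an activator when it jointly satisfies:
#'
#' 1. H3.3 deposition onset on the successful route falls in the onset window
#'    (default D6 to D12 onwards);
#' 2. it is never enriched at any sorted unsuccessful-route time-point
#'    (route exclusivity);
#' 3. its expression increases along the successful route exclusively
#'    (successful endpoint log2 fold change `>= lfc_min`, unsuccessful
#'    `|log2FC| < lfc_min`).
#'
#' @param h33_onsets Output of [onset_calls()] for the H3.3 modality.
#' @param h33_presence Presence-matrix tibble covering the unsuccessful
#'   samples.
#' @param expr FPKM signal-matrix tibble.
#' @param sheet Sample-sheet tibble.
#' @param onset_window Admissible onset labels (default `D6T-`, `D9T-`,
#'   `D12S+`).
#' @param lfc_min Log2 fold-change threshold (default 1).
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return Tibble with one row per gene: `gene_id`, the three criterion
#'   columns and `is_activator`.
#' @export
identify_activators <- function(h33_onsets, h33_presence, expr, sheet,
                                onset_window = c("D6T-", "D9T-", "D12S+"),
                                lfc_min = 1, pseudocount = 1) {
  if (missing(h33_onsets) || missing(h33_presence) || missing(expr)) {
    rlang::abort("h33_onsets, h33_presence and expr are all required")
  }
  excl <- route_exclusive_calls(h33_presence, sheet)
  de <- endpoint_de(expr, sheet, lfc_min = lfc_min, pseudocount = pseudocount)
  out <- h33_onsets |>
    dplyr::select("gene_id", "status", "onset_label") |>
    dplyr::left_join(excl, by = "gene_id") |>
    dplyr::left_join(de, by = "gene_id") |>
    dplyr::mutate(
      onset_in_window = .data$status == "onset" &
        .data$onset_label %in% onset_window,
      expr_up_exclusive = .data$log2fc_successful >= lfc_min &
        abs(.data$log2fc_unsuccessful) < lfc_min,
      is_activator = .data$onset_in_window &
        !is.na(.data$route_exclusive) & .data$route_exclusive &
        .data$expr_up_exclusive
    )
  dplyr::select(out, "gene_id", "onset_in_window", "route_exclusive",
                "expr_up_exclusive", "is_activator")
}

#' Hypergeometric marker-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene set against each named
#' marker set within a universe (a cell-type enrichment in the style of
#' marker-database tools), with Benjamini-Hochberg adjustment across sets and
#' an enrichment score of `-log10(adjusted p)`.  Scores at or above
#' `significance_score` (default 2) are flagged significant.
#'
#' @param query Character vector of gene ids; must be a subset of `universe`.
#' @param marker_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the universe are dropped.
#' @param universe Character vector of all assayed gene ids.
#' @param significance_score Score threshold for the `significant` flag.
#' @return Tibble `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `adjusted_p`, `score`, `significant`.
#' @export
marker_enrichment <- function(query, marker_sets, universe,
                              significance_score = 2) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    rlang::abort("query genes must all belong to the universe")
  }
  if (is.null(names(marker_sets)) || any(names(marker_sets) == "")) {
    rlang::abort("marker_sets must be a named list")
  }
  rows <- purrr::imap(marker_sets, function(set, name) {
    set <- intersect(unique(set), universe)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1L, length(set),
                       length(universe) - length(set), length(query),
                       lower.tail = FALSE)
    tibble::tibble(set_name = name, overlap = ov, set_size = length(set),
                   query_size = length(query),
                   universe_size = length(universe), p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$score <- -log10(out$adjusted_p)
  out$significant <- out$score >= significance_score
  out
}

#' Read and write GMT marker-set files
#'
#' GMT format: one set per line — set name, description, then gene ids, all
#' tab separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed GMT line ", bad[1L], " in ", path))
  }
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
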