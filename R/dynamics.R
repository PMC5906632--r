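#' Endpoint differential-expression gate
#'
#' Computes per-gene endpoint log2 fold changes against day 0 on both routes:
#' `log2((endpoint + pseudocount) / (D0 + pseudocount))`, where the successful
#' endpoint is the last sample of the successful route (iPSC in the default
#' design) and the unsuccessful endpoint is the last sorted unsuccessful
#' sample.  A gene is differentially expressed (`is_de`) when the successful
#' log2 fold change reaches `lfc_min` in magnitude.
#'
#' @param expr FPKM signal-matrix tibble (RNA assay samples as columns).
#' @param sheet Sample-sheet tibble.
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param pseudocount Pseudocount guarding zero FPKM (default 1).
#' @param assay Assay of the expression samples (default `"rna"`).
#' @return Tibble `gene_id`, `log2fc_successful`, `log2fc_unsuccessful`,
#'   `is_de`.
#' @export
endpoint_de <- function(expr, sheet, lfc_min = 1, pseudocount = 1,
                        assay = "rna") {
  validate_signal_matrix(expr)
  succ <- route_labels(sheet, "successful", assay = assay)
  has_unsucc <- any(sheet$route == "unsuccessful" & sheet$assay == assay)
  unsucc_end <- if (has_unsucc) {
    u <- route_labels(sheet, "unsuccessful", assay = assay,
                      include_shared = FALSE)
    u[length(u)]
  }
  d0 <- succ[1L]
  ends <- c(succ[length(succ)], unsucc_end)
  absent <- setdiff(c(d0, ends), names(expr))
  if (length(absent) > 0L) {
    rlang::abort(paste0("expression matrix missing endpoint sample(s): ",
                        paste(absent, collapse = ", ")))
  }
  base <- expr[[d0]] + pseudocount
  lfc_s <- log2((expr[[ends[1L]]] + pseudocount) / base)
  lfc_u <- if (has_unsucc) {
    log2((expr[[unsucc_end]] + pseudocount) / base)
  } else {
    rep(NA_real_, nrow(expr))
  }
  tibble::tibble(
    gene_id = expr$gene_id,
    log2fc_successful = lfc_s,
    log2fc_unsuccessful = lfc_u,
    is_de = abs(lfc_s) >= lfc_min
  )
}

#' Route-dependent Cluster I-IV assignment
#'
#' Assigns differentially expressed genes to the four route-dependent
#' trajectory classes:
#'
#' * **I** — down on both routes;
#' * **II** — down exclusively on the successful route (unsuccessful flat or
#'   up);
#' * **III** — up on both routes;
#' * **IV** — up exclusively on the successful route (unsuccessful flat or
#'   down).
#'
#' "Down"/"up" mean the endpoint log2 fold change reaches `-lfc_min` /
#' `+lfc_min`.  Genes that are not differentially expressed, or whose
#' unsuccessful-route fold change is missing, are `unassigned`.
#'
#' @param de Output of [endpoint_de()].
#' @param lfc_min Log2 fold-change threshold (default 1).
#' @return Tibble `gene_id`, `cluster` (factor `I`, `II`, `III`, `IV`,
#'   `unassigned`).
#' @export
assign_cluster <- function(de, lfc_min = 1) {
  s <- de$log2fc_successful
  u <- de$log2fc_unsuccessful
  s_down <- s <= -lfc_min
  s_up <- s >= lfc_min
  u_down <- u <= -lfc_min
  u_up <- u >= lfc_min
  label <- dplyr::case_when(
    !de$is_de | is.na(u) ~ "unassigned",
    s_down & u_down ~ "I",
    s_down & !u_down ~ "II",
    s_up & u_up ~ "III",
    s_up & !u_up ~ "IV",
    .default = "unassigned"
  )
  tibble::tibble(
    gene_id = de$gene_id,
    cluster = factor(label, levels = c("I", "II", "III", "IV", "unassigned"))
  )
}

#' Deterministic row ordering for cluster heatmaps
#'
#' Orders genes by cluster label (I, II, III, IV, then unassigned) and, within
#' each cluster, by the leaf order of average-linkage hierarchical clustering
#' on Euclidean distances of the row-normalised values.  Rows are sorted by
#' `gene_id` before clustering so the ordering is invariant to the input row
#' permutation; exact ties fall back to `gene_id` order.
#'
#' @param matrix Row-normalised signal-matrix tibble.
#' @param clusters Output of [assign_cluster()]; optional — without it all
#'   genes are ordered in one clustering pass.
#' @return Character vector of gene ids in display order.
#' @export
order_rows_for_heatmap <- function(matrix, clusters = NULL) {
  validate_signal_matrix(matrix)
  v <- sm_values(matrix)
  lab <- if (is.null(clusters)) {
    rep("all", nrow(matrix))
  } else {
    as.character(clusters$cluster[match(matrix$gene_id, clusters$gene_id)])
  }
  levels <- if (is.null(clusters)) "all" else {
    c("I", "II", "III", "IV", "unassigned")
  }
  order_block <- function(ids) {
    ids <- sort(ids)
    if (length(ids) <= 2L) return(ids)
    # cluster distinct row patterns so exact ties keep gene_id order
    key <- apply(v[ids, , drop = FALSE], 1L, paste, collapse = "\r")
    groups <- split(ids, factor(key, levels = unique(key)))
    if (length(groups) <= 2L) return(unlist(groups, use.names = FALSE))
    reps <- v[vapply(groups, `[[`, "", 1L), , drop = FALSE]
    h <- stats::hclust(stats::dist(reps), method = "average")
    unlist(groups[h$order], use.names = FALSE)
  }
  unlist(lapply(levels, function(l) order_block(matrix$gene_id[lab == l])),
         use.names = FALSE)
}

#' Cluster heatmap of a row-normalised matrix
#'
#' Tile heatmap of a row-normalised signal matrix with genes in
#' [order_rows_for_heatmap()] order.
#'
#' @param matrix Row-normalised signal-matrix tibble.
#' @param clusters Optional output of [assign_cluster()].
#' @return A ggplot object.
#' @export
plot_cluster_heatmap <- function(matrix, clusters = NULL) {
  ord <- order_rows_for_heatmap(matrix, clusters)
  long <- tidyr::pivot_longer(matrix, -"gene_id",
                              names_to = "sample", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = rev(ord))
  long$sample <- factor(long$sample, levels = names(matrix)[-1L])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#08306b", mid = "#f7f7f7",
                                  high = "#a50f15", midpoint = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "row-norm.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
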