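#' "D-onwards" onset classification of a presence trajectory
#'
#' Classifies an ordered boolean presence vector along a route (first element
#' = day 0) into one of four statuses:
#'
#' * `constitutive` — present at day 0 (such genes never receive an onset:
#'   only genes that *start* displaying enrichment after day 0 qualify);
#' * `never` — absent at every time-point;
#' * `onset` — absent at day 0 and every point before some time-point `t`,
#'   then present at `t` and every later point through the end of the course
#'   (the gene is "`t` onwards");
#' * `unsustained` — any other pattern (gained then lost, or gapped).
#'
#' @param presence Logical (or 0/1) vector, ordered along the route.
#' @param labels Sample labels matching `presence`; used for `onset_label`.
#' @return One-row tibble `status`, `onset_label` (`NA` unless `status` is
#'   `"onset"`).
#' @export
#' @examples
#' classify_onset(c(0, 1, 1, 1, 1, 1, 1),
#'                c("D0", "D3", "D6T-", "D9T-", "D12S+", "D16S+", "iPSC"))
classify_onset <- function(presence, labels = NULL) {
  if (length(presence) == 0L) rlang::abort("presence vector must be non-empty")
  p <- as.logical(presence)
  if (anyNA(p)) rlang::abort("presence vector must not contain NA")
  if (is.null(labels)) labels <- paste0("t", seq_along(p) - 1L)
  if (length(labels) != length(p)) {
    rlang::abort("labels must match the presence vector length")
  }
  if (p[1L]) {
    status <- "constitutive"
    onset <- NA_character_
  } else if (!any(p)) {
    status <- "never"
    onset <- NA_character_
  } else {
    t <- which(p)[1L]
    if (all(p[t:length(p)])) {
      status <- "onset"
      onset <- labels[t]
    } else {
      status <- "unsustained"
      onset <- NA_character_
    }
  }
  tibble::tibble(status = status, onset_label = onset)
}

#' Expression onset at an FPKM threshold
#'
#' A gene qualifies only if its day-0 FPKM is at or below `threshold`.  With
#' `sustained = FALSE` (the default, matching the "at any time-point after
#' day 0" wording) the onset is the first post-day-0 time-point with FPKM
#' above the threshold.  With `sustained = TRUE` the onset is the first
#' time-point from which expression stays above the threshold through the end
#' of the course; transient earlier crossings are ignored (unlike the
#' deposition rule, which declares gapped patterns unsustained), and a gene
#' never above threshold at the end is `never`.
#'
#' @param fpkm Numeric vector ordered along the route (first element day 0).
#' @param labels Sample labels matching `fpkm`.
#' @param threshold FPKM threshold; expression counts when FPKM > threshold
#'   (default 1).
#' @param sustained Require expression at every point from onset to the end?
#' @return One-row tibble `status`, `onset_label`.
#' @export
#' @examples
#' expression_onset(c(0.2, 0.5, 1.3, 2.0, 5.1, 8.0, 9.9),
#'                  c("D0", "D3", "D6T-", "D9T-", "D12S+", "D16S+", "iPSC"))
expression_onset <- function(fpkm, labels = NULL, threshold = 1,
                             sustained = FALSE) {
  if (length(fpkm) == 0L) rlang::abort("fpkm vector must be non-empty")
  if (is.null(labels)) labels <- paste0("t", seq_along(fpkm) - 1L)
  expressed <- fpkm > threshold
  if (expressed[1L]) {
    return(tibble::tibble(status = "constitutive", onset_label = NA_character_))
  }
  n <- length(expressed)
  hits <- if (sustained) {
    # first point from which expression persists through the end
    sustained_from <- rev(cumprod(rev(expressed))) == 1
    which(sustained_from[-1L]) + 1L
  } else {
    which(expressed[-1L]) + 1L
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(status = "never", onset_label = NA_character_))
  }
  tibble::tibble(status = "onset", onset_label = labels[hits[1L]])
}

#' Route exclusivity of enrichment
#'
#' A gene is route-exclusive when it is *not* enriched at any sorted
#' unsuccessful-route time-point.  Shared (pre-sorting) samples are excluded
#' from the check since they cannot distinguish routes.  An empty unsuccessful
#' vector yields `NA` (undefined), never `TRUE`.
#'
#' @param presence_successful Logical vector along the successful route
#'   (unused by the rule; accepted for interface symmetry and validated for
#'   non-emptiness).
#' @param presence_unsuccessful Logical vector over the sorted
#'   unsuccessful-route samples only.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
route_exclusive <- function(presence_successful, presence_unsuccessful) {
  if (length(presence_unsuccessful) == 0L) return(NA)
  !any(as.logical(presence_unsuccessful))
}

#' Deposition-versus-expression precedence
#'
#' Compares the H3.3 deposition onset with the expression onset of a gene on
#' the same route ordering.  `lead` is the number of time-point steps by which
#' deposition precedes expression (`index(expression onset) - index(deposition
#' onset)`); the relation is `deposition_first` when positive, `simultaneous`
#' at zero, `expression_first` when negative, and `undefined` when either
#' modality lacks an onset.
#'
#' @param h33_call,expr_call One-row tibbles from [classify_onset()] /
#'   [expression_onset()].
#' @param labels Route sample labels the onset labels index into.
#' @return One-row tibble `relation`, `lead` (`NA` when undefined).
#' @export
precedence <- function(h33_call, expr_call, labels) {
  if (h33_call$status != "onset" || expr_call$status != "onset") {
    return(tibble::tibble(relation = "undefined", lead = NA_integer_))
  }
  i_h <- match(h33_call$onset_label, labels)
  i_e <- match(expr_call$onset_label, labels)
  if (is.na(i_h) || is.na(i_e)) {
    rlang::abort("onset labels must appear in the route labels")
  }
  lead <- i_e - i_h
  relation <- if (lead > 0L) "deposition_first" else if (lead == 0L) {
    "simultaneous"
  } else {
    "expression_first"
  }
  tibble::tibble(relation = relation, lead = as.integer(lead))
}

#' Onset calls for every gene of a matrix
#'
#' Applies the onset rule of the given modality to each row of a presence or
#' signal matrix along the successful route.  H3.3 and accessibility use the
#' sustained "D-onwards" rule on presence calls; expression uses the FPKM
#' threshold rule.
#'
#' @param matrix Presence-matrix tibble (for `"h33"`) or numeric
#'   signal-matrix tibble (for `"expression"` / `"accessibility"`).
#' @param sheet Sample-sheet tibble.
#' @param modality One of `"h33"`, `"expression"`, `"accessibility"`.
#' @param threshold FPKM / accessibility threshold (default 1; ignored for
#'   `"h33"`).
#' @param sustained Passed to [expression_onset()] for `"expression"`;
#'   accessibility always uses the sustained rule ("in a similar fashion" to
#'   deposition).
#' @param assay Assay whose route ordering to use.
#' @return Tibble `gene_id`, `modality`, `status`, `onset_label`.
#' @export
onset_calls <- function(matrix, sheet,
                        modality = c("h33", "expression", "accessibility"),
                        threshold = 1, sustained = FALSE,
                        assay = NULL) {
  modality <- rlang::arg_match(modality)
  if (is.null(assay)) {
    assay <- switch(modality, h33 = "chip_ip", expression = "rna",
                    accessibility = "atac")
  }
  labels <- route_labels(sheet, "successful", assay = assay)
  absent <- setdiff(labels, names(matrix))
  if (length(absent) > 0L) {
    rlang::abort(paste0("matrix missing successful-route sample(s): ",
                        paste(absent, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(matrix)), function(i) {
    x <- unlist(matrix[i, labels], use.names = FALSE)
    switch(modality,
      h33 = classify_onset(x, labels),
      expression = expression_onset(x, labels, threshold = threshold,
                                    sustained = sustained),
      accessibility = classify_onset(x > threshold, labels)
    )
  })
  dplyr::bind_cols(
    tibble::tibble(gene_id = matrix$gene_id, modality = modality),
    dplyr::bind_rows(rows)
  )
}

#' Route exclusivity for every gene of a presence matrix
#'
#' @param presence Presence-matrix tibble covering the unsuccessful samples.
#' @param sheet Sample-sheet tibble.
#' @param assay Assay whose unsuccessful samples to use.
#' @return Tibble `gene_id`, `route_exclusive` (logical, `NA` if the design
#'   has no unsuccessful branch).
#' @export
route_exclusive_calls <- function(presence, sheet, assay = "chip_ip") {
  has_unsucc <- any(sheet$route == "unsuccessful" & sheet$assay == assay)
  if (!has_unsucc) {
    return(tibble::tibble(gene_id = presence$gene_id, route_exclusive = NA))
  }
  labels <- route_labels(sheet, "unsuccessful", assay = assay,
                         include_shared = FALSE)
  absent <- setdiff(labels, names(presence))
  if (length(absent) > 0L) {
    rlang::abort(paste0("presence matrix missing unsuccessful sample(s): ",
                        paste(absent, collapse = ", ")))
  }
  v <- as.matrix(presence[labels])
  tibble::tibble(gene_id = presence$gene_id,
                 route_exclusive = rowSums(v) == 0)
}

#' Deposition-versus-expression precedence for every gene
#'
#' @param h33_onsets,expr_onsets Outputs of [onset_calls()] for the two
#'   modalities (same genes).
#' @param sheet Sample-sheet tibble.
#' @param assay Assay giving the route ordering (default `"chip_ip"`; the
#'   bundled designs share labels across assays).
#' @return Tibble `gene_id`, `relation`, `lead`.
#' @export
precedence_calls <- function(h33_onsets, expr_onsets, sheet,
                             assay = "chip_ip") {
  labels <- route_labels(sheet, "successful", assay = assay)
  joined <- dplyr::inner_join(
    dplyr::select(h33_onsets, "gene_id", h_status = "status",
                  h_label = "onset_label"),
    dplyr::select(expr_onsets, "gene_id", e_status = "status",
                  e_label = "onset_label"),
    by = "gene_id"
  )
  both <- joined$h_status == "onset" & joined$e_status == "onset"
  lead <- rep(NA_integer_, nrow(joined))
  lead[both] <- match(joined$e_label[both], labels) -
    match(joined$h_label[both], labels)
  relation <- dplyr::case_when(
    !both ~ "undefined",
    lead > 0L ~ "deposition_first",
    lead == 0L ~ "simultaneous",
    .default = "expression_first"
  )
  tibble::tibble(gene_id = joined$gene_id, relation = relation, lead = lead)
}
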