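#' Library-size normalisation of tag counts
#'
#' Scales each sample column to a common library size:
#' `value * scale / library_size`, the convention used for "normalized tag
#' counts" over gene regions (default scale 1e7 tags).
#'
#' @param counts Signal-matrix tibble of raw tag counts.
#' @param library_sizes Named numeric vector of total tags per sample; names
#'   must cover every sample column.
#' @param scale Target library size (default `1e7`).
#' @return A signal-matrix tibble of normalised counts.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "g1", D0 = 100)
#' normalize_library(m, c(D0 = 2e7))  # -> 50
normalize_library <- function(counts, library_sizes, scale = 1e7) {
  validate_signal_matrix(counts)
  samples <- names(counts)[-1L]
  missing <- setdiff(samples, names(library_sizes))
  if (length(missing) > 0L) {
    rlang::abort(paste0("library_sizes missing sample(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(library_sizes[samples] <= 0)) {
    rlang::abort("library sizes must be > 0")
  }
  for (s in samples) counts[[s]] <- counts[[s]] * scale / library_sizes[[s]]
  counts
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = counts / ((gene_length / 1e3) * (library_size / 1e6))`.
#'
#' @param counts Numeric vector (or signal-matrix tibble) of fragment counts.
#' @param gene_length Gene length(s) in bp; for a matrix input, a named
#'   vector covering every `gene_id`.
#' @param library_size Total mapped fragments per sample (scalar for vector
#'   input; named vector for matrix input).
#' @return FPKM values in the same shape as `counts`.
#' @export
#' @examples
#' compute_fpkm(100, 2000, 1e6)  # -> 50
compute_fpkm <- function(counts, gene_length, library_size) {
  if (any(gene_length <= 0)) rlang::abort("gene_length must be > 0")
  if (any(library_size <= 0)) rlang::abort("library_size must be > 0")
  if (is.data.frame(counts)) {
    validate_signal_matrix(counts)
    len <- gene_length[counts$gene_id]
    if (anyNA(len)) rlang::abort("gene_length missing for some gene_id")
    for (s in names(counts)[-1L]) {
      ls <- if (length(library_size) == 1L) library_size else library_size[[s]]
      counts[[s]] <- unname(counts[[s]] / ((len / 1e3) * (ls / 1e6)))
    }
    return(counts)
  }
  counts / ((gene_length / 1e3) * (library_size / 1e6))
}

#' Call fold-over-input enrichment
#'
#' A gene is called present in a sample when
#' `(ip + pseudocount) / (input + pseudocount) >= fold` and the IP signal
#' density (normalised tags per kb of genebody) is at least `min_density`.
#' The density floor suppresses spurious 2-over-1 calls on near-empty genes;
#' set `min_density = 0` for the bare fold rule.
#'
#' @param ip,input Library-normalised signal-matrix tibbles with identical
#'   gene order and sample columns.
#' @param gene_lengths Named vector of genebody lengths in bp (required when
#'   `min_density > 0`).
#' @param fold Fold-change-over-input threshold (default 2).
#' @param min_density Minimum IP density, normalised tags per kb (default 0.5).
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return A presence-matrix tibble (logical sample columns).
#' @export
call_enrichment <- function(ip, input, gene_lengths = NULL, fold = 2,
                            min_density = 0.5, pseudocount = 1) {
  validate_signal_matrix(ip)
  validate_signal_matrix(input)
  if (!identical(names(ip), names(input)) ||
      !identical(ip$gene_id, input$gene_id)) {
    rlang::abort("ip and input matrices must share gene order and sample labels")
  }
  ip_v <- sm_values(ip)
  in_v <- sm_values(input)
  present <- (ip_v + pseudocount) / (in_v + pseudocount) >= fold
  if (min_density > 0) {
    if (is.null(gene_lengths)) {
      rlang::abort("gene_lengths is required when min_density > 0")
    }
    len <- gene_lengths[ip$gene_id]
    if (anyNA(len)) rlang::abort("gene_lengths missing for some gene_id")
    density <- ip_v / (len / 1e3)
    present <- present & (density >= min_density)
  }
  out <- tibble::as_tibble(present)
  dplyr::bind_cols(tibble::tibble(gene_id = ip$gene_id), out)
}

#' Per-row min-max normalisation
#'
#' Rescales each gene row to `[0, 1]` via `(x - min) / (max - min)`; constant
#' rows map to all zero.  Used for heatmap display of FPKM and tag-count
#' matrices.
#'
#' @param matrix Signal-matrix tibble.
#' @return Row-normalised signal-matrix tibble.
#' @export
#' @examples
#' row_normalize(tibble::tibble(gene_id = "g", a = 2, b = 4, c = 6))
row_normalize <- function(matrix) {
  validate_signal_matrix(matrix)
  v <- sm_values(matrix)
  if (nrow(v) > 0L) {
    lo <- apply(v, 1L, min)
    hi <- apply(v, 1L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1  # constant rows -> 0 after centring
    v <- (v - lo) / rng
  }
  sm_rebuild(v, matrix$gene_id)
}
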