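#' Sample sheets for branching time-course designs
#'
#' A sample sheet is a tibble with one row per sample and assay, with columns
#' `label` (sample label, used as column name in signal matrices), `day`
#' (integer day post induction), `route` (`"shared"`, `"successful"` or
#' `"unsuccessful"`) and `assay` (`"chip_ip"`, `"chip_input"`, `"rna"` or
#' `"atac"`).  Day-0 samples are always `shared`; the two routes diverge once
#' cells are sorted.
#'
#' `design_reprogramming()` builds the default seven-point fibroblast-to-iPSC
#' design: shared D0 and D3, then the sorted successful route (Thy-1 negative,
#' SSEA-1 positive: D6T-, D9T-, D12S+, D16S+, iPSC) alongside the sorted
#' unsuccessful route (D6T+, D9T+, D12S-, D16S-).  `design_transdiff()` builds
#' the three-point fibroblast-to-iHP transdifferentiation design (day 0,
#' day 4, iHP), which has no unsuccessful branch.
#'
#' @param assays Character vector of assays to include.
#' @return A sample-sheet tibble.
#' @export
#' @examples
#' design_reprogramming()
design_reprogramming <- function(assays = c("chip_ip", "chip_input", "rna", "atac")) {
  base <- tibble::tibble(
    label = c("D0", "D3", "D6T-", "D9T-", "D12S+", "D16S+", "iPSC",
              "D6T+", "D9T+", "D12S-", "D16S-"),
    day   = c(0L, 3L, 6L, 9L, 12L, 16L, 20L, 6L, 9L, 12L, 16L),
    route = c("shared", "shared", rep("successful", 5L), rep("unsuccessful", 4L))
  )
  sheet <- tidyr::expand_grid(assay = assays, base) |>
    dplyr::select("label", "day", "route", "assay") |>
    dplyr::arrange(.data$assay, .data$day, .data$route)
  validate_sample_sheet(sheet)
}

#' @rdname design_reprogramming
#' @export
design_transdiff <- function(assays = c("chip_ip", "chip_input", "rna", "atac")) {
  base <- tibble::tibble(
    label = c("day0", "day4", "iHP"),
    day   = c(0L, 4L, 8L),
    route = c("shared", "successful", "successful")
  )
  sheet <- tidyr::expand_grid(assay = assays, base) |>
    dplyr::select("label", "day", "route", "assay") |>
    dplyr::arrange(.data$assay, .data$day)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' Checks column presence and types, route values, non-decreasing days within
#' each route, and that each assay has exactly one shared day-0 sample.
#'
#' @param sheet A sample-sheet tibble (see [design_reprogramming()]).
#' @return The validated sheet, invisibly unchanged.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("label", "day", "route", "assay")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    rlang::abort(paste0("sample sheet is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!all(sheet$route %in% c("shared", "successful", "unsuccessful"))) {
    rlang::abort("sample sheet route must be shared, successful or unsuccessful")
  }
  if (!all(sheet$assay %in% c("chip_ip", "chip_input", "rna", "atac"))) {
    rlang::abort("sample sheet assay must be chip_ip, chip_input, rna or atac")
  }
  if (any(sheet$day < 0L)) rlang::abort("sample sheet days must be >= 0")
  ok_d0 <- sheet |>
    dplyr::group_by(.data$assay) |>
    dplyr::summarise(
      n0 = sum(.data$day == 0L & .data$route == "shared"),
      .groups = "drop"
    )
  if (!all(ok_d0$n0 == 1L)) {
    rlang::abort("each assay needs exactly one shared day-0 sample")
  }
  unsorted <- sheet |>
    dplyr::group_by(.data$assay, .data$route) |>
    dplyr::summarise(bad = is.unsorted(.data$day), .groups = "drop")
  if (any(unsorted$bad)) {
    rlang::abort("days must be non-decreasing within each route")
  }
  invisible(sheet)
}

#' Ordered sample labels along a route
#'
#' Returns the sample labels of one assay in time order along the requested
#' route.  The successful route includes the shared pre-sorting samples
#' (day 0 and day 3 in the default design) followed by the sorted successful
#' samples; `include_shared = FALSE` restricts to the sorted samples only,
#' which is the convention for the route-exclusivity check on the
#' unsuccessful branch.
#'
#' @param sheet Sample-sheet tibble.
#' @param route `"successful"` or `"unsuccessful"`.
#' @param assay Assay to select (default `"chip_ip"`; labels are shared
#'   across assays in the bundled designs).
#' @param include_shared Include the shared (pre-bifurcation) samples?
#' @return Character vector of ordered sample labels.
#' @export
#' @examples
#' route_labels(design_reprogramming(), "successful")
#' route_labels(design_reprogramming(), "unsuccessful", include_shared = FALSE)
route_labels <- function(sheet, route = c("successful", "unsuccessful"),
                         assay = "chip_ip", include_shared = TRUE) {
  route <- rlang::arg_match(route)
  validate_sample_sheet(sheet)
  keep <- if (include_shared) c("shared", route) else route
  sel <- sheet |>
    dplyr::filter(.data$assay == !!assay, .data$route %in% keep) |>
    dplyr::arrange(.data$day)
  if (nrow(sel) == 0L) {
    rlang::abort(paste0("no samples for assay '", assay, "' on route '", route, "'"))
  }
  sel$label
}

#' Read and write sample sheets
#'
#' Sample sheets are stored as TSV with columns `label`, `day`, `route`,
#' `assay`.
#'
#' @param path File path.
#' @param sheet Sample-sheet tibble.
#' @return `read_sample_sheet()` returns a validated sample-sheet tibble;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    label = readr::col_character(),
    day = readr::col_integer(),
    route = readr::col_character(),
    assay = readr::col_character()
  ))
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_tsv(sheet, path)
  invisible(path)
}
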