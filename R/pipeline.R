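#' Pipeline run configuration
#'
#' Collects input/output locations and every analysis threshold, each at its
#' field-standard default: 3000 bp promoter window, fold-over-input 2,
#' FPKM threshold 1, |log2FC| threshold 1, top-250 loss ranking, marker
#' enrichment-score cutoff 2.  The configuration hash stamped into every
#' output file is computed over all analysis-relevant fields, so identical
#' configurations yield identical, auditable bundles.
#'
#' @param input_dir Directory holding a bundle (see [simulate_bundle()] for
#'   the layout).
#' @param output_dir Directory for pipeline outputs (created if needed).
#' @param promoter_bp Promoter window (bp upstream of TSS).
#' @param fold Fold-over-input enrichment threshold.
#' @param min_density Minimum IP density (normalised tags/kb).
#' @param pseudocount Pseudocount for fold changes and enrichment calls.
#' @param fpkm_threshold Expression-onset FPKM threshold.
#' @param lfc_min Log2 fold-change threshold for DE and clustering.
#' @param top_n Size of the top-loss ranking.
#' @param significance_score Marker-enrichment score cutoff.
#' @param onset_window Admissible activator onset labels.
#' @param expression_sustained Use the sustained expression-onset rule?
#' @param normalization_scale Library-normalisation target (tags).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       promoter_bp = 3000L, fold = 2, min_density = 0.5,
                       pseudocount = 1, fpkm_threshold = 1, lfc_min = 1,
                       top_n = 250L, significance_score = 2,
                       onset_window = c("D6T-", "D9T-", "D12S+"),
                       expression_sustained = FALSE,
                       normalization_scale = 1e7) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir,
    promoter_bp = as.integer(promoter_bp), fold = fold,
    min_density = min_density, pseudocount = pseudocount,
    fpkm_threshold = fpkm_threshold, lfc_min = lfc_min,
    top_n = as.integer(top_n), significance_score = significance_score,
    onset_window = onset_window,
    expression_sustained = expression_sustained,
    normalization_scale = normalization_scale
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg),
                                      c("input_dir", "output_dir"))])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$hash, "\n  input:", x$input_dir,
      "\n  output:", x$output_dir, "\n")
  invisible(x)
}

# write a tibble with the config-hash header comment
write_output <- function(tbl, path, config) {
  readr::write_lines(paste0("# config_hash: ", config$hash), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_bundle_inputs <- function(config) {
  ind <- config$input_dir
  need <- c("sample_sheet.tsv", "genes.bed", "h33_ip.tsv", "h33_input.tsv",
            "fpkm.tsv")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing) > 0L) {
    rlang::abort(paste0("input bundle is missing: ",
                        paste(missing, collapse = ", ")))
  }
  sheet <- read_sample_sheet(file.path(ind, "sample_sheet.tsv"))
  libs_path <- file.path(ind, "library_sizes.tsv")
  library_sizes <- if (file.exists(libs_path)) {
    t <- readr::read_tsv(libs_path, col_types = "cd")
    stats::setNames(t$library_size, t$label)
  } else {
    NULL
  }
  atac_path <- file.path(ind, "atac.tsv")
  gmt_path <- file.path(ind, "markers.gmt")
  list(
    sheet = sheet,
    genes = read_gene_models(file.path(ind, "genes.bed")),
    h33_ip = read_matrix(file.path(ind, "h33_ip.tsv"), sheet),
    h33_input = read_matrix(file.path(ind, "h33_input.tsv"), sheet),
    fpkm = read_matrix(file.path(ind, "fpkm.tsv"), sheet),
    atac = if (file.exists(atac_path)) read_matrix(atac_path, sheet),
    library_sizes = library_sizes,
    marker_sets = if (file.exists(gmt_path)) read_gmt(gmt_path)
  )
}

stage_log <- function(stage, ...) {
  message("[h33dyn] ", stage, ": ", ...)
}

#' Pipeline stages
#'
#' Each stage is a thin, logged wrapper over the corresponding analysis
#' functions: it reads its inputs from the bundle, writes its outputs (TSV
#' with a config-hash header) into `output_dir`, and returns them invisibly.
#' [run_all()] is exactly the composition of the stages, so running stages
#' individually and running the full pipeline produce identical files.
#'
#' * `stage_annotate()` — peak-to-region assignment and category distribution
#'   per ChIP sample;
#' * `stage_quantify()` — library normalisation, fold-over-input presence
#'   calls, row-normalised FPKM;
#' * `stage_clusters()` — endpoint DE and Cluster I-IV labels plus heatmap
#'   row order;
#' * `stage_onset()` — onset calls for deposition/expression/accessibility,
#'   route exclusivity, precedence;
#' * `stage_discover()` — top-loss ranking, activators, marker enrichment;
#' * `stage_profiles()` — gene-set trajectories and a TSS profile.
#'
#' @param config A [run_config()].
#' @param inputs Optional pre-read bundle (internal use).
#' @return Stage outputs, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_annotate <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  peak_dir <- file.path(config$input_dir, "peaks")
  chip <- unique(inputs$sheet$label[inputs$sheet$assay == "chip_ip"])
  per_sample <- purrr::map(chip, function(s) {
    path <- file.path(peak_dir, paste0(sample_file_stem(s), ".bed"))
    if (!file.exists(path)) return(NULL)
    peaks <- read_peaks(path)
    assigned <- assign_region(peaks, inputs$genes,
                              promoter_bp = config$promoter_bp)
    dplyr::mutate(assigned, sample_label = s, .before = 1L)
  })
  assigned <- dplyr::bind_rows(per_sample)
  if (nrow(assigned) > 0L) {
    dist <- assigned |>
      dplyr::group_by(.data$sample_label) |>
      dplyr::count(.data$category, .drop = FALSE) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    write_output(assigned, file.path(config$output_dir,
                                     "region_assignments.tsv"), config)
    write_output(dist, file.path(config$output_dir,
                                 "region_distribution.tsv"), config)
    stage_log("annotate", nrow(assigned), " peak assignments over ",
              length(unique(assigned$sample_label)), " sample(s)")
  } else {
    stage_log("annotate", "no peak files found; stage skipped")
  }
  invisible(assigned)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ip <- inputs$h33_ip
  input <- inputs$h33_input
  if (!is.null(inputs$library_sizes)) {
    ip <- normalize_library(ip, inputs$library_sizes,
                            scale = config$normalization_scale)
    input <- normalize_library(input, inputs$library_sizes,
                               scale = config$normalization_scale)
  }
  gene_lengths <- stats::setNames(inputs$genes$end - inputs$genes$start,
                                  inputs$genes$gene_id)
  presence <- call_enrichment(ip, input, gene_lengths,
                              fold = config$fold,
                              min_density = config$min_density,
                              pseudocount = config$pseudocount)
  fpkm_rn <- row_normalize(inputs$fpkm)
  write_output(ip, file.path(config$output_dir, "h33_normalized.tsv"), config)
  presence_out <- dplyr::mutate(presence, dplyr::across(-"gene_id",
                                                        as.integer))
  write_output(presence_out,
               file.path(config$output_dir, "presence_h33.tsv"), config)
  write_output(fpkm_rn, file.path(config$output_dir, "fpkm_rownorm.tsv"),
               config)
  stage_log("quantify", nrow(presence), " genes, ",
            sum(as.matrix(presence[-1L])), " presence calls")
  invisible(list(h33_norm = ip, input_norm = input, presence = presence,
                 fpkm_rownorm = fpkm_rn))
}

#' @rdname pipeline_stages
#' @export
stage_clusters <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  de <- endpoint_de(inputs$fpkm, inputs$sheet, lfc_min = config$lfc_min,
                    pseudocount = config$pseudocount)
  clusters <- assign_cluster(de, lfc_min = config$lfc_min)
  ord <- order_rows_for_heatmap(row_normalize(inputs$fpkm), clusters)
  write_output(de, file.path(config$output_dir, "de.tsv"), config)
  write_output(clusters, file.path(config$output_dir, "clusters.tsv"), config)
  readr::write_lines(c(paste0("# config_hash: ", config$hash), ord),
                     file.path(config$output_dir, "heatmap_order.txt"))
  stage_log("clusters", sum(de$is_de), " DE genes; cluster sizes ",
            paste(table(clusters$cluster)[1:4], collapse = "/"))
  invisible(list(de = de, clusters = clusters, order = ord))
}

#' @rdname pipeline_stages
#' @export
stage_onset <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  q <- stage_quantify(config, inputs)
  h33 <- onset_calls(q$presence, inputs$sheet, "h33")
  expr <- onset_calls(inputs$fpkm, inputs$sheet, "expression",
                      threshold = config$fpkm_threshold,
                      sustained = config$expression_sustained)
  excl <- route_exclusive_calls(q$presence, inputs$sheet)
  prec <- precedence_calls(h33, expr, inputs$sheet)
  write_output(h33, file.path(config$output_dir, "onset_h33.tsv"), config)
  write_output(expr, file.path(config$output_dir, "onset_expr.tsv"), config)
  write_output(excl, file.path(config$output_dir, "route_exclusive.tsv"),
               config)
  write_output(prec, file.path(config$output_dir, "precedence.tsv"), config)
  atac_onsets <- NULL
  if (!is.null(inputs$atac)) {
    atac_onsets <- onset_calls(inputs$atac, inputs$sheet, "accessibility",
                               threshold = config$fpkm_threshold)
    write_output(atac_onsets,
                 file.path(config$output_dir, "onset_atac.tsv"), config)
  }
  stage_log("onset", sum(h33$status == "onset"), " deposition-onset genes, ",
            sum(prec$relation == "deposition_first"), " deposition-first")
  invisible(list(h33 = h33, expr = expr, atac = atac_onsets,
                 route_exclusive = excl, precedence = prec,
                 presence = q$presence, h33_norm = q$h33_norm))
}

#' @rdname pipeline_stages
#' @export
stage_discover <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  o <- stage_onset(config, inputs)
  top <- rank_h33_loss(o$h33_norm, inputs$sheet, n = config$top_n)
  act <- identify_activators(o$h33, o$presence, inputs$fpkm, inputs$sheet,
                             onset_window = config$onset_window,
                             lfc_min = config$lfc_min,
                             pseudocount = config$pseudocount)
  write_output(top, file.path(config$output_dir, "top_loss.tsv"), config)
  write_output(act, file.path(config$output_dir, "activators.tsv"), config)
  readr::write_lines(c(paste0("# config_hash: ", config$hash),
                       act$gene_id[act$is_activator]),
                     file.path(config$output_dir, "activator_genes.txt"))
  enr <- NULL
  if (!is.null(inputs$marker_sets)) {
    enr <- marker_enrichment(act$gene_id[act$is_activator],
                             inputs$marker_sets,
                             universe = inputs$fpkm$gene_id,
                             significance_score = config$significance_score)
    write_output(enr, file.path(config$output_dir, "marker_enrichment.tsv"),
                 config)
  }
  stage_log("discover", sum(act$is_activator), " activators; top-",
            nrow(top), " loss table")
  invisible(list(top_loss = top, activators = act, enrichment = enr,
                 onset = o))
}

#' @rdname pipeline_stages
#' @export
stage_profiles <- function(config, inputs = read_bundle_inputs(config)) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  q <- stage_quantify(config, inputs)
  out <- list()
  if (!is.null(inputs$marker_sets)) {
    for (set in names(inputs$marker_sets)) {
      genes <- intersect(inputs$marker_sets[[set]], q$h33_norm$gene_id)
      if (length(genes) == 0L) next
      traj <- geneset_trajectory(q$h33_norm, inputs$sheet, genes,
                                 route = "successful", geneset_name = set)
      write_output(traj, file.path(config$output_dir,
                                   paste0("trajectory_", set, ".tsv")),
                   config)
      out[[set]] <- traj
    }
  }
  cov_dir <- file.path(config$input_dir, "coverage")
  cov_files <- if (dir.exists(cov_dir)) {
    sort(list.files(cov_dir, pattern = "\\.bedgraph$", full.names = TRUE))
  } else {
    character()
  }
  if (length(cov_files) > 0L) {
    cov <- read_bedgraph(cov_files[1L])
    anchors <- tibble::tibble(
      chrom = inputs$genes$chrom,
      position = ifelse(inputs$genes$strand == "+", inputs$genes$start,
                        inputs$genes$end),
      strand = inputs$genes$strand
    )
    prof <- suppressWarnings(bin_signal(cov, anchors, flank = 2000L,
                                        n_bins = 40L))
    write_output(prof, file.path(config$output_dir, "profile_tss.tsv"),
                 config)
    out$profile_tss <- prof
  }
  stage_log("profiles", length(out), " profile/trajectory table(s)")
  invisible(out)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a bundle directory — annotation, quantification,
#' clustering, onset/precedence, discovery, profiles — and writes a manifest
#' recording the effective configuration (so paper-default versus override is
#' always auditable), the configuration hash stamped into every output file,
#' and the package version.  The run is a pure function of the inputs and the
#' configuration: identical configs give byte-identical output bundles.
#'
#' @param config A [run_config()].
#' @return An object of class `h33_run` (named list of all stage outputs),
#'   invisibly.
#' @export
run_all <- function(config) {
  inputs <- read_bundle_inputs(config)
  annotated <- stage_annotate(config, inputs)
  clusters <- stage_clusters(config, inputs)
  discovery <- stage_discover(config, inputs)  # runs quantify + onset inside
  profiles <- stage_profiles(config, inputs)
  # the manifest records the effective analysis parameters, not run-local
  # paths, so identical configurations yield identical manifests
  fields <- unclass(config)[setdiff(names(unclass(config)),
                                    c("input_dir", "output_dir"))]
  scalar <- vapply(fields, function(x) length(x) == 1L, TRUE)
  manifest <- tibble::tibble(
    key = c("tool_version", names(fields)[scalar], "onset_window"),
    value = c(as.character(utils::packageVersion("h33dyn")),
              vapply(fields[scalar], as.character, ""),
              paste(config$onset_window, collapse = ","))
  )
  write_output(manifest, file.path(config$output_dir, "manifest.tsv"), config)
  stage_log("run_all", "complete; manifest hash ", config$hash)
  res <- list(config = config, annotated = annotated, clusters = clusters,
              discovery = discovery, profiles = profiles)
  class(res) <- "h33_run"
  invisible(res)
}

#' @export
print.h33_run <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Summaries of a pipeline run
#'
#' `glance()` returns a one-row overview of a completed [run_all()] result;
#' `tidy()` returns the per-gene call table joining clusters, onsets,
#' exclusivity and activator status.
#'
#' @param x A `h33_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.h33_run <- function(x, ...) {
  cl <- table(x$clusters$clusters$cluster)
  act <- x$discovery$activators
  tibble::tibble(
    n_genes = nrow(act),
    n_de = sum(x$clusters$de$is_de),
    n_cluster_I = as.integer(cl[["I"]]),
    n_cluster_II = as.integer(cl[["II"]]),
    n_cluster_III = as.integer(cl[["III"]]),
    n_cluster_IV = as.integer(cl[["IV"]]),
    n_onset = sum(x$discovery$onset$h33$status == "onset"),
    n_deposition_first =
      sum(x$discovery$onset$precedence$relation == "deposition_first"),
    n_activators = sum(act$is_activator),
    config_hash = x$config$hash
  )
}

#' @rdname glance.h33_run
#' @exportS3Method generics::tidy
tidy.h33_run <- function(x, ...) {
  o <- x$discovery$onset
  x$clusters$clusters |>
    dplyr::left_join(dplyr::select(o$h33, "gene_id",
                                   h33_status = "status",
                                   h33_onset = "onset_label"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::select(o$expr, "gene_id",
                                   expr_status = "status",
                                   expr_onset = "onset_label"),
                     by = "gene_id") |>
    dplyr::left_join(o$route_exclusive, by = "gene_id") |>
    dplyr::left_join(dplyr::select(o$precedence, "gene_id", "relation",
                                   "lead"), by = "gene_id") |>
    dplyr::left_join(dplyr::select(x$discovery$activators, "gene_id",
                                   "is_activator"), by = "gene_id")
}
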