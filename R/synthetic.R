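#' Configuration for the synthetic branching time course
#'
#' Bundles every knob of the generator.  Defaults emulate the structure of a
#' bifurcating fibroblast-to-iPSC reprogramming course: six gene classes
#' (fibroblast, mesenchymal, pluripotency, epithelial, housekeeping, neutral),
#' lognormal multiplicative noise on FPKM and accessibility, negative-binomial
#' overdispersion on ChIP tag counts, an independent per-entry presence-flip
#' rate `presence_flip`, and the fraction of onset genes whose H3.3
#' deposition leads their expression onset.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions over the six classes; must sum to 1.
#'   Class counts are allocated deterministically by largest remainder, so
#'   realised counts match the fractions to rounding.
#' @param fpkm_log_sd Standard deviation of lognormal noise on FPKM and
#'   accessibility (natural-log scale; 0 = noise free).
#' @param count_dispersion Negative-binomial dispersion of ChIP counts
#'   (`size = 1/dispersion`; 0 = counts equal their expectation).
#' @param presence_flip Probability of flipping each planted presence call
#'   before count generation (`[0, 0.5)`).
#' @param deposition_lead_fraction Fraction of onset genes whose deposition
#'   onset precedes their expression onset (the rest are simultaneous).
#' @param seed Mandatory integer seed; the whole bundle is a deterministic
#'   function of the configuration.
#' @param design `"reprogramming"` (7-point bifurcating) or `"transdiff"`
#'   (3-point, no unsuccessful branch).
#' @param expr_high,expr_low High/low FPKM template levels.  The defaults
#'   (3.8, 0.2) put planted endpoint log2 fold changes at exactly +/-2 under
#'   the pseudocount-1 rule and straddle the FPKM > 1 onset threshold.
#' @param input_density Expected input tags per kb of genebody.
#' @param enrich_fold Expected IP/input ratio at enriched genes (>= 2 so the
#'   fold-over-input caller recovers planted presence exactly at zero noise).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              class_fractions = c(fibroblast = 0.15,
                                                  mesenchymal = 0.10,
                                                  pluripotency = 0.15,
                                                  epithelial = 0.10,
                                                  housekeeping = 0.10,
                                                  neutral = 0.40),
                              fpkm_log_sd = 0.25,
                              count_dispersion = 0.1,
                              presence_flip = 0.02,
                              deposition_lead_fraction = 0.8,
                              seed,
                              design = c("reprogramming", "transdiff"),
                              expr_high = 3.8, expr_low = 0.2,
                              input_density = 2, enrich_fold = 4) {
  design <- rlang::arg_match(design)
  if (missing(seed)) rlang::abort("seed is mandatory")
  classes <- c("fibroblast", "mesenchymal", "pluripotency", "epithelial",
               "housekeeping", "neutral")
  if (!setequal(names(class_fractions), classes)) {
    rlang::abort(paste0("class_fractions must name exactly: ",
                        paste(classes, collapse = ", ")))
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    rlang::abort("class_fractions must sum to 1")
  }
  if (presence_flip < 0 || presence_flip >= 0.5) {
    rlang::abort("presence_flip must lie in [0, 0.5)")
  }
  if (deposition_lead_fraction < 0 || deposition_lead_fraction > 1) {
    rlang::abort("deposition_lead_fraction must lie in [0, 1]")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    class_fractions = class_fractions[classes],
    fpkm_log_sd = fpkm_log_sd,
    count_dispersion = count_dispersion,
    presence_flip = presence_flip,
    deposition_lead_fraction = deposition_lead_fraction,
    seed = as.integer(seed),
    design = design,
    expr_high = expr_high, expr_low = expr_low,
    input_density = input_density, enrich_fold = enrich_fold
  ), class = "sim_config")
}

#' Generate a random non-overlapping gene catalog
#'
#' Gene lengths are log-uniform in 1-50 kb, strands random, placements
#' non-overlapping within each chromosome, and the whole catalog a
#' deterministic function of the seed.
#'
#' @param n_genes Number of genes.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param seed Integer seed.
#' @return Gene-catalog tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
generate_genome <- function(n_genes,
                            chrom_lengths = c(chr1 = 6e7, chr2 = 5e7,
                                              chr3 = 4e7),
                            seed = 1L) {
  if (n_genes == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  withr::with_seed(seed, {
    lengths <- round(exp(stats::runif(n_genes, log(1e3), log(5e4))))
    chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    idx_by_chrom <- split(seq_len(n_genes), chrom)
    start <- integer(n_genes)
    for (ch in names(idx_by_chrom)) {
      idx <- idx_by_chrom[[ch]]
      slack <- chrom_lengths[[ch]] - sum(lengths[idx])
      if (slack < 0) {
        rlang::abort(paste0("gene footprint does not fit chromosome ", ch))
      }
      w <- stats::runif(length(idx) + 1L)
      gaps <- floor(w / sum(w) * slack)
      start[idx] <- utils::head(cumsum(gaps + c(0L, lengths[idx])), -1L)
    }
    width <- max(4L, nchar(as.character(n_genes)))
    tibble::tibble(
      gene_id = sprintf(paste0("g%0", width, "d"), seq_len(n_genes)),
      chrom = chrom,
      start = as.integer(start),
      end = as.integer(start + lengths),
      strand = strand
    )
  })
}

# injective file stem for a sample label: +/- sorting markers spelled out
sample_file_stem <- function(label) {
  s <- gsub("\\+", "pos", label)
  s <- gsub("-", "neg", s)
  gsub("[^A-Za-z0-9]+", "_", s)
}

# successful / unsuccessful-only labels for a design
design_sheet <- function(config) {
  switch(config$design,
         reprogramming = design_reprogramming(),
         transdiff = design_transdiff())
}

#' Plant per-gene ground truth
#'
#' Assigns each gene a class (counts matching the configured fractions to
#' rounding), a route-dependent expression cluster consistent with the class
#' (fibroblast/mesenchymal genes go down, so Cluster I or II; pluripotency/
#' epithelial genes go up, so Cluster III or IV; housekeeping and neutral
#' genes are flat), an H3.3 deposition onset and an expression onset for the
#' gaining classes (expression lags deposition by 1-2 steps for a
#' `deposition_lead_fraction` of onset genes, simultaneous otherwise), an
#' activator flag (route-exclusive pluripotency Cluster IV genes with onset in
#' the D6-D12 window), and a repressor flag (fibroblast Cluster II genes).
#' Epithelial genes are planted with unsuccessful-route enrichment, so
#' activators arise only in the pluripotency class.
#'
#' @param config A `sim_config` (see [simulation_config()]).
#' @return Tibble of class `h33_truth`: `gene_id`, `class`, `planted_cluster`,
#'   `planted_h33_onset`, `planted_expr_onset`, `is_activator`,
#'   `is_repressor`.
#' @export
generate_truth <- function(config) {
  sheet <- design_sheet(config)
  succ <- route_labels(sheet, "successful")
  n <- config$n_genes
  onset_window <- intersect(c("D6T-", "D9T-", "D12S+"), succ)
  withr::with_seed(config$seed + 1L, {
    # largest-remainder class allocation, then a random permutation
    target <- config$class_fractions * n
    counts <- floor(target)
    left <- n - sum(counts)
    if (left > 0L) {
      extra <- order(target - counts, decreasing = TRUE)[seq_len(left)]
      counts[extra] <- counts[extra] + 1L
    }
    class <- sample(rep(names(counts), counts))

    down <- class %in% c("fibroblast", "mesenchymal")
    up <- class %in% c("pluripotency", "epithelial")
    cluster <- rep("none", n)
    cluster[down] <- sample(c("I", "II"), sum(down), replace = TRUE)
    cluster[up] <- sample(c("III", "IV"), sum(up), replace = TRUE)

    # deposition onsets for gaining classes: any post-day-0 point with room
    # for an expression lag of at least one step
    onset_pool <- succ[2:max(2L, length(succ) - 2L)]
    h_idx <- rep(NA_integer_, n)
    up_idx <- which(up)
    n_up <- length(up_idx)
    h_idx[up] <- match(sample(onset_pool, n_up, replace = TRUE), succ)
    # exact allocation of the deposition-lead fraction, then random placement
    lead <- rep(0L, n)
    n_lead <- round(config$deposition_lead_fraction * n_up)
    lead_genes <- up_idx[sample.int(n_up, n_lead)]
    lead[lead_genes] <- sample(1:2, n_lead, replace = TRUE)
    lead[up] <- pmin(lead[up], length(succ) - h_idx[up])
    e_idx <- h_idx + lead

    width <- max(4L, nchar(as.character(n)))
    truth <- tibble::tibble(
      gene_id = sprintf(paste0("g%0", width, "d"), seq_len(n)),
      class = class,
      planted_cluster = cluster,
      planted_h33_onset = ifelse(is.na(h_idx), NA_character_, succ[h_idx]),
      planted_expr_onset = ifelse(is.na(e_idx), NA_character_, succ[e_idx]),
      is_activator = class == "pluripotency" & cluster == "IV" &
        !is.na(h_idx) & succ[pmax(h_idx, 1L)] %in% onset_window,
      is_repressor = class == "fibroblast" & cluster == "II"
    )
    structure(truth, class = c("h33_truth", class(truth)))
  })
}

# planted presence pattern of one gene over (successful, unsuccessful-only)
planted_presence <- function(class, cluster, h_idx, n_succ, n_unsucc,
                             loss_idx = NULL) {
  succ <- rep(FALSE, n_succ)
  unsucc <- rep(FALSE, max(n_unsucc, 0L))
  if (class == "housekeeping") {
    succ[] <- TRUE
    unsucc[] <- TRUE
  } else if (class %in% c("fibroblast", "mesenchymal")) {
    # enriched from day 0, lost from loss_idx on the successful route;
    # retained throughout the unsuccessful route
    succ[seq_len(loss_idx - 1L)] <- TRUE
    unsucc[] <- TRUE
  } else if (class %in% c("pluripotency", "epithelial")) {
    succ[h_idx:n_succ] <- TRUE
    if (n_unsucc > 0L) {
      if (class == "epithelial" || cluster == "III") {
        # gains enrichment on the unsuccessful branch too (not exclusive)
        unsucc[pmax(n_unsucc - 1L, 1L):n_unsucc] <- TRUE
      }
    }
  }
  # neutral: never enriched
  list(succ = succ, unsucc = unsucc)
}

# piecewise-constant FPKM template over (successful, unsuccessful-only);
# cluster decides the unsuccessful branch: I/III change on both routes,
# II/IV change on the successful route exclusively
planted_fpkm <- function(class, cluster, e_idx, n_succ, n_unsucc,
                         loss_idx, hi, lo) {
  succ <- rep(lo, n_succ)
  unsucc <- rep(lo, max(n_unsucc, 0L))
  if (class == "housekeeping") {
    succ[] <- hi + 2
    unsucc[] <- hi + 2
  } else if (class %in% c("fibroblast", "mesenchymal")) {
    succ[] <- hi
    succ[loss_idx:n_succ] <- lo
    if (n_unsucc > 0L) unsucc[] <- if (cluster == "I") lo else hi
  } else if (class %in% c("pluripotency", "epithelial")) {
    succ[e_idx:n_succ] <- hi
    if (n_unsucc > 0L) unsucc[] <- if (cluster == "III") hi else lo
  }
  # neutral: constant low on both routes
  list(succ = succ, unsucc = unsucc)
}

#' Simulate the full matrix bundle
#'
#' Generates, deterministically from the configuration seed, the gene catalog
#' and the gene-by-sample matrices of a branching time course: H3.3 IP and
#' input tag counts (negative binomial around `enrich_fold` times the input
#' expectation wherever the — possibly flip-perturbed — planted presence
#' pattern is on), FPKM and accessibility (class templates times lognormal
#' noise), together with per-sample peak tables and stepwise coverage.  At
#' zero noise the analysis modules recover every planted label exactly.
#'
#' @param config A `sim_config`.
#' @param truth Optional pre-generated truth table (from [generate_truth()]).
#' @param genes Optional pre-generated catalog (from [generate_genome()]).
#' @return A list of class `h33_sim` with elements `config`, `sheet`, `genes`,
#'   `truth`, `h33_ip`, `h33_input`, `fpkm`, `atac` (signal-matrix tibbles),
#'   `library_sizes`, `peaks` (named list of peak tibbles per ChIP sample),
#'   `coverage` (named list of `stepwise_coverage`), `marker_sets`.
#' @export
simulate_matrices <- function(config, truth = generate_truth(config),
                              genes = generate_genome(config$n_genes,
                                                      seed = config$seed)) {
  if (nrow(truth) != config$n_genes || nrow(genes) != config$n_genes) {
    rlang::abort("truth/genes dimensions must match config$n_genes")
  }
  sheet <- design_sheet(config)
  succ <- route_labels(sheet, "successful")
  unsucc_labels <- if (any(sheet$route == "unsuccessful")) {
    route_labels(sheet, "unsuccessful", include_shared = FALSE)
  } else {
    character()
  }
  all_labels <- c(succ, unsucc_labels)
  n <- config$n_genes
  n_s <- length(succ)
  n_u <- length(unsucc_labels)
  lengths_bp <- stats::setNames(genes$end - genes$start, genes$gene_id)

  withr::with_seed(config$seed + 2L, {
    # losing classes shed enrichment/expression at a balanced spread of time
    # steps, so every consecutive step of a class trajectory loses some genes
    loss_idx <- integer(n)
    for (cl in c("fibroblast", "mesenchymal")) {
      idx <- which(truth$class == cl)
      if (length(idx) > 0L) {
        steps <- rep_len(2:n_s, length(idx))
        loss_idx[idx] <- steps[sample.int(length(idx))]
      }
    }
    h_idx <- match(truth$planted_h33_onset, succ)
    e_idx <- match(truth$planted_expr_onset, succ)

    presence <- matrix(FALSE, n, n_s + n_u,
                       dimnames = list(truth$gene_id, all_labels))
    fpkm_t <- matrix(config$expr_low, n, n_s + n_u,
                     dimnames = list(truth$gene_id, all_labels))
    for (i in seq_len(n)) {
      pp <- planted_presence(truth$class[i], truth$planted_cluster[i],
                             h_idx[i], n_s, n_u, loss_idx[i])
      presence[i, ] <- c(pp$succ, pp$unsucc)
      ft <- planted_fpkm(truth$class[i], truth$planted_cluster[i],
                         e_idx[i], n_s, n_u, loss_idx[i],
                         config$expr_high, config$expr_low)
      fpkm_t[i, ] <- c(ft$succ, ft$unsucc)
    }

    # independent presence flips, applied before count generation so the
    # emitted counts carry the perturbed state
    if (config$presence_flip > 0) {
      flips <- matrix(stats::runif(length(presence)) < config$presence_flip,
                      nrow = n)
      presence <- xor(presence, flips)
      dimnames(presence) <- list(truth$gene_id, all_labels)
    }

    mu_input <- config$input_density * (lengths_bp[truth$gene_id] / 1e3)
    mu_input_m <- matrix(mu_input, n, n_s + n_u)
    mu_ip_m <- mu_input_m * ifelse(presence, config$enrich_fold, 1)
    draw <- function(mu) {
      if (config$count_dispersion == 0) return(mu)
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$count_dispersion), nrow = n)
    }
    ip <- draw(mu_ip_m)
    input <- draw(mu_input_m)
    dimnames(ip) <- dimnames(input) <- dimnames(presence)

    lognoise <- function(m) {
      if (config$fpkm_log_sd == 0) return(m)
      m * exp(matrix(stats::rnorm(length(m), 0, config$fpkm_log_sd), nrow = n))
    }
    fpkm <- lognoise(fpkm_t)
    # accessibility mirrors the deposition pattern on a continuous scale
    atac_t <- matrix(0.2, n, n_s + n_u, dimnames = dimnames(presence))
    atac_t[presence] <- 3.8
    atac <- lognoise(atac_t)

    peaks <- lapply(all_labels, function(s) {
      on <- presence[, s]
      tibble::tibble(
        chrom = genes$chrom[on], start = genes$start[on],
        end = genes$end[on], score = config$enrich_fold
      ) |> dplyr::arrange(.data$chrom, .data$start)
    })
    names(peaks) <- all_labels
    coverage <- lapply(all_labels, function(s) {
      dens <- ip[, s] / lengths_bp[truth$gene_id]
      tbl <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                            end = genes$end, value = dens) |>
        dplyr::filter(.data$value > 0) |>
        dplyr::arrange(.data$chrom, .data$start)
      stepwise_coverage(tbl)
    })
    names(coverage) <- all_labels

    marker_sets <- split(truth$gene_id, truth$class)
    marker_sets <- marker_sets[setdiff(names(marker_sets),
                                       c("housekeeping", "neutral"))]

    structure(list(
      config = config, sheet = sheet, genes = genes, truth = truth,
      h33_ip = sm_rebuild(ip), h33_input = sm_rebuild(input),
      fpkm = sm_rebuild(fpkm), atac = sm_rebuild(atac),
      library_sizes = stats::setNames(rep(1e7, n_s + n_u), all_labels),
      peaks = peaks, coverage = coverage, marker_sets = marker_sets
    ), class = "h33_sim")
  })
}

#' @export
print.h33_sim <- function(x, ...) {
  cat("<h33_sim>", x$config$n_genes, "genes,", x$config$design, "design,",
      "seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Materialises a simulation as the plain-text formats the pipeline consumes:
#' `genes.bed`, `sample_sheet.tsv`, `h33_ip.tsv`, `h33_input.tsv`,
#' `fpkm.tsv`, `atac.tsv`, `library_sizes.tsv`, `truth.tsv`, `markers.gmt`,
#' plus `peaks/<label>.bed` and `coverage/<label>.bedgraph` per ChIP sample.
#'
#' @param sim A `h33_sim` from [simulate_matrices()], or a `sim_config`
#'   (which is then simulated first).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_bundle <- function(sim, dir) {
  if (inherits(sim, "sim_config")) sim <- simulate_matrices(sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  write_gene_models(sim$genes, file.path(dir, "genes.bed"))
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"))
  write_matrix(sim$h33_ip, file.path(dir, "h33_ip.tsv"))
  write_matrix(sim$h33_input, file.path(dir, "h33_input.tsv"))
  write_matrix(sim$fpkm, file.path(dir, "fpkm.tsv"))
  write_matrix(sim$atac, file.path(dir, "atac.tsv"))
  readr::write_tsv(tibble::tibble(label = names(sim$library_sizes),
                                  library_size = unname(sim$library_sizes)),
                   file.path(dir, "library_sizes.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_gmt(sim$marker_sets, file.path(dir, "markers.gmt"))
  for (s in names(sim$peaks)) {
    stem <- sample_file_stem(s)
    write_peaks(sim$peaks[[s]], file.path(dir, "peaks",
                                          paste0(stem, ".bed")))
    write_bedgraph(sim$coverage[[s]],
                   file.path(dir, "coverage", paste0(stem, ".bedgraph")))
  }
  invisible(dir)
}
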