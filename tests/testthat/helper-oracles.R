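# Independent brute-force oracles used by the dual-route tests.  These stay
# deliberately naive: literal rule application, per-base labelling and
# exhaustive enumeration, never sharing code with the package internals.

# literal D-onwards rule: try every candidate onset position and compare the
# whole pattern against the canonical "absent before t, present from t" shape
oracle_classify_onset <- function(p, labels = paste0("t", seq_along(p) - 1L)) {
  p <- as.logical(p)
  n <- length(p)
  if (p[1L]) return(list(status = "constitutive", onset_label = NA_character_))
  if (!any(p)) return(list(status = "never", onset_label = NA_character_))
  for (t in 2:n) {
    canonical <- c(rep(FALSE, t - 1L), rep(TRUE, n - t + 1L))
    if (identical(p, canonical)) {
      return(list(status = "onset", onset_label = labels[t]))
    }
  }
  list(status = "unsustained", onset_label = NA_character_)
}

# every boolean pattern of length n, as a list of logical vectors
all_patterns <- function(n) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# per-base region labeller: label every base of a toy genome by precedence
# (promoter > genebody > intergenic), then classify a peak by the highest-
# precedence label among its bases
oracle_base_labels <- function(genes, chrom_len, promoter_bp = 3000L) {
  lab <- rep(0L, chrom_len)  # 0 intergenic, 1 genebody, 2 promoter
  for (i in seq_len(nrow(genes))) {
    body <- (genes$start[i] + 1L):genes$end[i]  # 1-based positions
    lab[body] <- pmax(lab[body], 1L)
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      from <- max(0L, genes$start[i] - promoter_bp)
      to <- genes$start[i]
      if (to > from) win <- (from + 1L):to else next
    } else {
      from <- genes$end[i]
      to <- min(chrom_len, genes$end[i] + promoter_bp)
      if (to > from) win <- (from + 1L):to else next
    }
    lab[win] <- 2L
  }
  lab
}

oracle_assign_category <- function(lab, start, end) {
  best <- max(lab[(start + 1L):end])
  c("intergenic", "genebody", "promoter")[best + 1L]
}

# textbook step-up BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive hypergeometric upper tail by enumerating draws of size k from a
# labelled universe (feasible for |universe| <= 20)
oracle_hyper_upper <- function(overlap, set_size, universe_size, query_size) {
  universe <- seq_len(universe_size)
  inset <- universe <= set_size
  draws <- utils::combn(universe, query_size)
  hits <- colSums(matrix(inset[draws], nrow = query_size))
  mean(hits >= overlap)
}

# small deterministic fixtures ------------------------------------------------

toy_sheet <- function() design_reprogramming()

toy_matrix <- function(rows, labels = route_labels(toy_sheet(), "successful")) {
  m <- do.call(rbind, rows)
  colnames(m) <- labels
  tibble::as_tibble(cbind(tibble::tibble(gene_id = names(rows)),
                          tibble::as_tibble(m)))
}

zero_noise_config <- function(seed = 1L, n_genes = 300L, ...) {
  simulation_config(n_genes = n_genes, fpkm_log_sd = 0,
                    count_dispersion = 0, presence_flip = 0,
                    seed = seed, ...)
}

# run the analysis pipeline in memory on a simulation and score recovery
recover_from_sim <- function(sim) {
  cfg <- sim$config
  lengths <- stats::setNames(sim$genes$end - sim$genes$start,
                             sim$genes$gene_id)
  ip <- normalize_library(sim$h33_ip, sim$library_sizes)
  input <- normalize_library(sim$h33_input, sim$library_sizes)
  presence <- call_enrichment(ip, input, lengths)
  h33 <- onset_calls(presence, sim$sheet, "h33")
  expr <- onset_calls(sim$fpkm, sim$sheet, "expression")
  de <- endpoint_de(sim$fpkm, sim$sheet)
  clusters <- assign_cluster(de)
  act <- identify_activators(h33, presence, sim$fpkm, sim$sheet)
  prec <- precedence_calls(h33, expr, sim$sheet)
  list(presence = presence, h33 = h33, expr = expr, clusters = clusters,
       activators = act, precedence = prec, h33_norm = ip)
}

onset_recovery_rate <- function(sim, rec = recover_from_sim(sim)) {
  truth <- sim$truth
  planted <- ifelse(is.na(truth$planted_h33_onset), "",
                    truth$planted_h33_onset)
  recovered <- ifelse(is.na(rec$h33$onset_label), "", rec$h33$onset_label)
  # genes without a planted onset must come back without one, and vice versa
  mean(planted == recovered)
}
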