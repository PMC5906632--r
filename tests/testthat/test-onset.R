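succ7 <- c("D0", "D3", "D6T-", "D9T-", "D12S+", "D16S+", "iPSC")

test_that("D-onwards classification matches the quoted rule on key patterns", {
  expect_equal(classify_onset(c(0, 1, 1, 1, 1, 1, 1), succ7),
               tibble::tibble(status = "onset", onset_label = "D3"))
  expect_equal(classify_onset(rep(0, 7), succ7)$status, "never")
  expect_equal(classify_onset(c(1, 1, 1, 1, 1, 1, 1), succ7)$status,
               "constitutive")
  expect_equal(classify_onset(c(0, 0, 1, 0, 1, 1, 1), succ7)$status,
               "unsustained")
  # a day-0-present gene is constitutive even if later lost
  expect_equal(classify_onset(c(1, 1, 0, 0, 0, 0, 0), succ7)$status,
               "constitutive")
  expect_error(classify_onset(logical()), "non-empty")
})

test_that("classification equals the literal brute-force rule on all patterns", {
  for (design in list(succ7, c("day0", "day4", "iHP"))) {
    for (p in all_patterns(length(design))) {
      got <- classify_onset(p, design)
      want <- oracle_classify_onset(p, design)
      expect_identical(got$status, want$status)
      expect_identical(got$onset_label, want$onset_label)
    }
  }
  # the four statuses partition pattern space: 2^7 patterns, one status each
  statuses <- vapply(all_patterns(7L),
                     function(p) classify_onset(p, succ7)$status, "")
  expect_equal(sum(table(statuses)), 128L)
  expect_setequal(names(table(statuses)),
                  c("constitutive", "never", "onset", "unsustained"))
})

test_that("expression onset crosses FPKM > 1 after a quiet day 0", {
  x <- c(0.2, 0.5, 1.3, 2.0, 5.1, 8.0, 9.9)
  expect_equal(expression_onset(x, succ7)$onset_label, "D6T-")
  expect_equal(expression_onset(rep(0.5, 7), succ7)$status, "never")
  expect_equal(expression_onset(c(5, rep(0.1, 6)), succ7)$status,
               "constitutive")

  # existential vs sustained reading of a dip below threshold
  dip <- c(0.2, 0.5, 1.3, 0.4, 5.1, 8.0, 9.9)
  expect_equal(expression_onset(dip, succ7, sustained = FALSE)$onset_label,
               "D6T-")
  expect_equal(expression_onset(dip, succ7, sustained = TRUE)$onset_label,
               "D12S+")
  expect_error(expression_onset(numeric()), "non-empty")

  # both modes agree with literal rule application on thresholded vectors
  oracle_sustained <- function(x, labels) {
    e <- x > 1
    if (e[1]) return(list(status = "constitutive", onset_label = NA_character_))
    for (t in 2:length(e)) {
      if (all(e[t:length(e)])) {
        return(list(status = "onset", onset_label = labels[t]))
      }
    }
    list(status = "never", onset_label = NA_character_)
  }
  set.seed(23)
  for (i in 1:200) {
    fpkm <- runif(7, 0, 3)
    sust <- expression_onset(fpkm, succ7, sustained = TRUE)
    want <- oracle_sustained(fpkm, succ7)
    expect_identical(sust$status, want$status)
    expect_identical(sust$onset_label, want$onset_label)
    loose <- expression_onset(fpkm, succ7, sustained = FALSE)
    if (fpkm[1] > 1) {
      expect_identical(loose$status, "constitutive")
    } else if (any(fpkm[-1] > 1)) {
      expect_identical(loose$onset_label, succ7[which(fpkm > 1)[1]])
    } else {
      expect_identical(loose$status, "never")
    }
  }
})

test_that("route exclusivity requires absence at every unsuccessful point", {
  expect_true(route_exclusive(c(0, 1, 1, 1), c(0, 0, 0, 0)))
  expect_false(route_exclusive(c(0, 1, 1, 1), c(0, 1, 0, 0)))
  expect_true(is.na(route_exclusive(c(0, 1, 1), logical())))
})

test_that("precedence relations and leads follow onset index arithmetic", {
  h <- tibble::tibble(status = "onset", onset_label = "D3")
  e <- tibble::tibble(status = "onset", onset_label = "D9T-")
  got <- precedence(h, e, succ7)
  expect_equal(got$relation, "deposition_first")
  expect_equal(got$lead, 2L)

  same <- precedence(h, h, succ7)
  expect_equal(same$relation, "simultaneous")
  expect_equal(same$lead, 0L)

  rev <- precedence(e, h, succ7)
  expect_equal(rev$relation, "expression_first")
  expect_equal(rev$lead, -2L)

  none <- tibble::tibble(status = "never", onset_label = NA_character_)
  expect_equal(precedence(none, e, succ7)$relation, "undefined")
  expect_true(is.na(precedence(none, e, succ7)$lead))
})

test_that("matrix-level onset and exclusivity wrappers agree with per-gene calls", {
  sheet <- toy_sheet()
  all_labels <- c(route_labels(sheet, "successful"),
                  route_labels(sheet, "unsuccessful", include_shared = FALSE))
  pres <- tibble::tibble(gene_id = c("on6", "hk", "off"))
  rows <- rbind(c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0, 0),
                c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0))
  for (j in seq_along(all_labels)) pres[[all_labels[j]]] <- rows[, j] == 1
  calls <- onset_calls(pres, sheet, "h33")
  expect_equal(calls$status, c("onset", "constitutive", "never"))
  expect_equal(calls$onset_label, c("D6T-", NA, NA))

  excl <- route_exclusive_calls(pres, sheet)
  expect_equal(excl$route_exclusive, c(TRUE, FALSE, FALSE))

  # transdifferentiation design: no unsuccessful branch -> NA
  td <- design_transdiff()
  pres3 <- tibble::tibble(gene_id = "g", day0 = FALSE, day4 = TRUE,
                          iHP = TRUE)
  expect_equal(onset_calls(pres3, td, "h33")$onset_label, "day4")
  expect_true(is.na(route_exclusive_calls(pres3, td)$route_exclusive))
})

test_that("onset recovery is exact at zero noise and degrades with flip noise", {
  rate_at <- function(eps, seed) {
    cfg <- simulation_config(n_genes = 400L, fpkm_log_sd = 0,
                             count_dispersion = 0, presence_flip = eps,
                             seed = seed)
    onset_recovery_rate(simulate_matrices(cfg))
  }
  expect_equal(rate_at(0, 31L), 1)
  eps_grid <- c(0, 0.02, 0.05, 0.1)
  rates <- vapply(eps_grid, function(e) {
    mean(vapply(c(31L, 32L, 33L), function(s) rate_at(e, s), 0))
  }, 0)
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[4], rates[1])
})

test_that("recovered precedence fraction equals the planted lead fraction", {
  for (f in c(0, 0.5, 1)) {
    cfg <- zero_noise_config(seed = 77L, n_genes = 300L,
                             deposition_lead_fraction = f)
    sim <- simulate_matrices(cfg)
    rec <- recover_from_sim(sim)
    defined <- rec$precedence$relation != "undefined"
    got <- mean(rec$precedence$relation[defined] == "deposition_first")
    truth <- sim$truth
    h_i <- match(truth$planted_h33_onset, succ7)
    e_i <- match(truth$planted_expr_onset, succ7)
    planted <- mean((e_i - h_i)[!is.na(h_i)] > 0)
    expect_equal(got, planted)
    if (f %in% c(0, 1)) expect_equal(got, f)
  }
})
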