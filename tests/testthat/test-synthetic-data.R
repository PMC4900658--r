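test_that("simulator honours parameter boundaries and seed determinism", {
  base <- function(...) sim_config(n_lines = 8, n_markers = 100, seed = 1, ...)
  no_het <- simulate_reference_panel(base(residual_het = 0))
  expect_equal(sum(no_het$gm$calls == 1L, na.rm = TRUE), 0)
  no_miss <- simulate_reference_panel(base(missing_rate = 0))
  expect_equal(sum(is.na(no_miss$gm$calls)), 0)
  a <- simulate_reference_panel(base())
  b <- simulate_reference_panel(base())
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$gm$depth, b$gm$depth)
  expect_identical(a$truth$group, b$truth$group)
  expect_error(sim_config(n_lines = 2, n_groups = 5, seed = 1), "groups")
  expect_error(sim_config(n_lines = 5), "seed")
})

test_that("realized heterozygosity and missingness match configured rates", {
  cfg <- sim_config(n_lines = 40, n_markers = 2000, residual_het = 0.05,
                    missing_rate = 0.18, seed = 202)
  gm <- simulate_reference_panel(cfg)$gm
  n <- length(gm$calls)
  miss_hat <- mean(is.na(gm$calls))
  expect_lt(abs(miss_hat - 0.18), 3 * sqrt(0.18 * 0.82 / n))
  # het is applied before missing, so condition on non-missing calls
  het_hat <- mean(gm$calls == 1L, na.rm = TRUE)
  n_obs <- sum(!is.na(gm$calls))
  expect_lt(abs(het_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n_obs))
})

test_that("marker metadata respects the karyotype and depth model", {
  cfg <- sim_config(n_lines = 5, n_markers = 500, seed = 33)
  gm <- simulate_reference_panel(cfg)$gm
  expect_true(all(gm$markers$chrom %in% names(cfg$chromosomes)))
  expect_true(all(gm$markers$pos >= 1))
  expect_true(all(gm$markers$pos <= cfg$chromosomes[gm$markers$chrom]))
  expect_true(all(gm$depth >= 0))
  # the [2, 15] coverage band must actually bite at both tails
  expect_gt(sum(gm$depth < 2), 0)
  expect_gt(sum(gm$depth > 15), 0)
})

test_that("complete-linkage clustering recovers the planted group structure", {
  sim <- simulate_reference_panel(sim_config(n_lines = 40, n_markers = 500,
                                             n_groups = 3, divergence = 0.4,
                                             seed = 67))
  dm <- allele_sharing_distance(sim$gm)
  cut <- stats::cutree(stats::hclust(stats::as.dist(dm$d),
                                     method = "complete"), k = 3)
  truth <- sim$truth$group[names(cut)]
  agreement <- max(vapply(seq_len(6), function(i) {
    perm <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))[i, ]
    mean(perm[cut] == truth)
  }, numeric(1)))
  expect_gte(agreement, 0.95)
})

test_that("regenerations drift from the source at the configured rate", {
  sim <- simulate_reference_panel(sim_config(n_lines = 4, n_markers = 4000,
                                             missing_rate = 0,
                                             residual_het = 0, seed = 12))
  gm <- sim$gm
  frozen <- simulate_regenerations(gm, "L001", n_gens = 3, drift_rate = 0,
                                   seed = 1)
  src <- gm$calls[, "L001"]
  for (prof in frozen$profiles) expect_equal(unname(prof), unname(src))
  eps <- 0.02
  drifted <- simulate_regenerations(gm, "L001", n_gens = 1, drift_rate = eps,
                                    seed = 2)
  q <- drifted$profiles[[1]]
  sims <- sum(shared_alleles(q, src)) / (2 * length(src))
  se <- sqrt(eps * (1 - eps) / length(src))
  expect_lt(abs((1 - sims) - eps), 3 * se)
  expect_equal(drifted$lineage$parent, "L001")
})

test_that("purification halves residual heterozygosity each generation", {
  calls <- matrix(0L, 5000, 1)
  calls[seq_len(600)] <- 1L                      # 12% heterozygous line
  gm <- make_gm(calls)
  out <- simulate_regenerations(gm, "E01", n_gens = 2, purify = TRUE,
                                seed = 31)
  rate <- mean(out$profiles[[2]] == 1L)
  se <- sqrt(0.03 * 0.97 / 5000)
  expect_lt(abs(rate - 0.03), 3 * se)
})

test_that("off-type injection plants exactly what it records", {
  sim <- simulate_reference_panel(sim_config(n_lines = 4, n_markers = 20,
                                             missing_rate = 0,
                                             residual_het = 0, seed = 9))
  gm <- sim$gm
  inds <- entry_individuals(gm, "L001", 50)
  cont <- stats::setNames(gm$calls[, "L002"], gm$markers$marker_id)
  none <- inject_off_types(inds, cont, rate = 0, seed = 1)
  expect_identical(none$individuals, inds)
  expect_equal(none$truth$contaminated, character(0))
  all_in <- inject_off_types(inds, cont, rate = 1, seed = 1)
  expect_true(all(all_in$individuals == cont))
  expect_equal(length(all_in$truth$contaminated), 50)
  swapped <- inject_off_types(inds, cont, rate = 0,
                              label_swaps = list(c("L001_i001", "L001_i002")),
                              seed = 1)
  expect_equal(colnames(swapped$individuals)[1:2],
               c("L001_i002", "L001_i001"))
  expect_warning(inject_off_types(inds,
                                  stats::setNames(gm$calls[, "L001"],
                                                  gm$markers$marker_id),
                                  rate = 0.5, seed = 1),
                 "indistinguishable")
})

test_that("the full pipeline recovers planted mislabelings end to end", {
  sim <- simulate_reference_panel(sim_config(n_lines = 20, n_markers = 300,
                                             missing_rate = 0.05, seed = 71))
  gm <- sim$gm
  stats_df <- compute_marker_stats(gm)
  kept <- filter_markers(stats_df,
                         filter_thresholds(max_missing = 0.3, max_het = 0.2,
                                           coverage_range = NULL))
  res <- optimize_panel(gm, kept, size = 40, reps = 60, seed = 3)
  panel <- res$panels[[1]]
  expect_equal(res$evaluations[[1]]$proportion_undistinguished, 0)
  # queries: 17 true to label, 3 mislabeled (true source differs)
  labels <- gm$entries
  true_source <- labels
  true_source[c(2, 9, 15)] <- labels[c(9, 15, 2)]
  verdicts <- vapply(seq_along(labels), function(i) {
    regen <- simulate_regenerations(gm, true_source[i], n_gens = 1,
                                    drift_rate = 0.01, seed = 100 + i)
    assign_identity(regen$profiles[[1]], gm, panel = panel,
                    expected = labels[i])$verdict
  }, character(1))
  expect_equal(verdicts[c(2, 9, 15)], rep("MISLABELED", 3))
  expect_equal(verdicts[-c(2, 9, 15)], rep("MATCH", 17))
})
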