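toy_stats <- function() {
  data.frame(
    marker_id = paste0("m", 1:6),
    chrom = rep("1", 6),
    pos = 1:6,
    maf = c(0.02, 0.3, 0.3, 0.3, 0.3, 0.3),
    het_rate = c(0.02, 0.02, 0.15, 0.02, 0.02, 0.02),
    missing_rate = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
    pic = 0.3,
    coverage = c(1, 5, 5, 5, 20, 5),
    stringsAsFactors = FALSE
  )
}

test_that("stringent selection rules remove each offender for its own reason", {
  kept <- filter_markers(toy_stats(), filter_thresholds())
  expect_setequal(kept, c("m2", "m4", "m6"))
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$marker_id == "m1"],
               "missing rate above threshold")
  expect_equal(removed$reason[removed$marker_id == "m3"],
               "heterogeneity above threshold")
  expect_equal(removed$reason[removed$marker_id == "m5"],
               "coverage outside range")
})

test_that("loosest thresholds keep everything; impossible MAF keeps nothing", {
  all_kept <- filter_markers(toy_stats(),
                             filter_thresholds(max_missing = 1, min_maf = 0,
                                               max_het = 1,
                                               coverage_range = NULL,
                                               require_placed = FALSE))
  expect_equal(length(all_kept), 6)
  expect_warning(
    none <- filter_markers(toy_stats(),
                           filter_thresholds(max_missing = 1, min_maf = 0.6,
                                             max_het = 1,
                                             coverage_range = NULL,
                                             require_placed = FALSE)),
    "no markers")
  expect_equal(length(none), 0)
})

test_that("unplaced markers are removed when placement is required", {
  st <- toy_stats()
  st$chrom[2] <- "0"
  kept <- filter_markers(st, filter_thresholds())
  expect_setequal(kept, c("m4", "m6"))
})

test_that("K-means grouping separates constructed marker blocks", {
  # two blocks of markers with opposite call profiles across 10 entries
  block1 <- matrix(rep(c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L), 8),
                   8, 10, byrow = TRUE)
  block2 <- matrix(rep(c(2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L), 8),
                   8, 10, byrow = TRUE)
  jitter <- matrix(rbinom(160, 1, 0.05) * 1L, 16, 10)
  calls <- pmin(rbind(block1, block2) + jitter, 2L)
  gm <- make_gm(calls)
  grp <- group_markers(gm, k = 2, n_components = 2, seed = 4)
  g <- grp$assignment
  expect_true(all(g[1:8] == g[1]) && all(g[9:16] == g[9]) && g[1] != g[9])
  # determinism under the seed
  grp2 <- group_markers(gm, k = 2, n_components = 2, seed = 4)
  expect_identical(grp$assignment, grp2$assignment)
})

test_that("grouping handles the singleton extreme and refuses k > profiles", {
  calls <- rbind(c(0L, 0L, 2L), c(2L, 0L, 0L), c(0L, 2L, 2L), c(2L, 2L, 0L))
  gm <- make_gm(calls)
  grp <- group_markers(gm, k = 4, n_components = 2, seed = 1)
  expect_equal(length(unique(grp$assignment)), 4)
  same <- make_gm(rbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(0L, 2L, 0L)))
  expect_error(group_markers(same, k = 3, seed = 1), "distinct")
})

test_that("allocation strategies produce their defining count patterns", {
  fake_groups <- function(sizes, scores) {
    assignment <- rep(seq_along(sizes), sizes)
    names(assignment) <- sprintf("m%03d", seq_along(assignment))
    structure(list(assignment = assignment,
                   centroids = matrix(0, length(sizes), 2),
                   distance_score = scores, k = length(sizes), seed = 1),
              class = "marker_groups")
  }
  g <- fake_groups(c(10, 10, 10), c(1, 2, 3))
  pgd <- allocate_by_strategy(g, 12, "PGD", seed = 1)
  expect_equal(pgd$counts, c(2L, 4L, 6L))
  ng <- allocate_by_strategy(fake_groups(c(5, 5, 5, 5), c(1, 1, 1, 1)),
                             8, "NG", seed = 1)
  expect_equal(ng$counts, rep(2L, 4))
  pg <- allocate_by_strategy(fake_groups(c(50, 50), c(1, 9)), 10, "PG",
                             seed = 1)
  expect_equal(pg$counts, c(5L, 5L))
  # PGD with equal scores degenerates to NG
  eq <- allocate_by_strategy(fake_groups(c(7, 9, 4), c(2, 2, 2)), 9, "PGD",
                             seed = 1)
  expect_equal(eq$counts, rep(3L, 3))
  # counts always sum to the total, markers unique and group-consistent
  for (total in c(3, 7, 13)) {
    out <- allocate_by_strategy(g, total, "PGD", seed = total)
    expect_equal(sum(out$counts), total)
    expect_equal(length(out$marker_ids), total)
    expect_false(anyDuplicated(out$marker_ids) > 0)
  }
  rnd <- allocate_by_strategy(g, 12, "RANDOM", seed = 2)
  expect_equal(sum(rnd$counts), 12)
})

test_that("a group smaller than its allocation forfeits the deficit", {
  assignment <- rep(1:3, c(2, 20, 20))
  names(assignment) <- sprintf("m%03d", seq_along(assignment))
  g <- structure(list(assignment = assignment,
                      centroids = matrix(0, 3, 2),
                      distance_score = c(10, 1, 1), k = 3, seed = 1),
                 class = "marker_groups")
  out <- allocate_by_strategy(g, 12, "PGD", seed = 1)
  expect_equal(sum(out$counts), 12)
  expect_lte(out$counts[1], 2)
  expect_gt(out$reallocated, 0)
})

test_that("uniform genomic selection picks bin-midpoint markers", {
  mk <- data.frame(marker_id = c("a", "b", "c"), chrom = "1",
                   pos = c(10L, 50L, 90L), stringsAsFactors = FALSE)
  picked <- select_uniform_genomic(mk, 2, chrom_lengths = c(`1` = 100))
  expect_equal(picked, c("a", "c"))
  expect_setequal(select_uniform_genomic(mk, 3), c("a", "b", "c"))
  # two equal-length chromosomes split the quota evenly
  mk2 <- data.frame(marker_id = paste0("m", 1:8),
                    chrom = rep(c("1", "2"), each = 4),
                    pos = rep(c(10L, 30L, 60L, 90L), 2),
                    stringsAsFactors = FALSE)
  picked2 <- select_uniform_genomic(mk2, 4,
                                    chrom_lengths = c(`1` = 100, `2` = 100))
  expect_equal(sum(picked2 %in% paste0("m", 1:4)), 2)
  expect_equal(sum(picked2 %in% paste0("m", 5:8)), 2)
  expect_error(select_uniform_genomic(mk, 5), "exceeds")
  mk$chrom[1] <- "0"
  expect_error(select_uniform_genomic(mk, 2), "placed")
})

test_that("panel evaluation counts undistinguished pairs as defined", {
  # L1 and L2 identical on the panel, L3 differs from both
  calls <- cbind(c(0L, 2L), c(0L, 2L), c(2L, 0L))
  colnames(calls) <- c("L1", "L2", "L3")
  gm <- make_gm(calls)
  ev <- evaluate_panel(gm, gm$markers$marker_id)
  expect_equal(ev$proportion_undistinguished, 1 / 3)
  expect_equal(ev$undistinguished_pairs, cbind("L1", "L2"))
  expect_equal(ev$min_mismatch, 0)
  # a panel separating everything
  calls2 <- cbind(c(0L, 0L), c(2L, 0L), c(0L, 2L))
  ev2 <- evaluate_panel(make_gm(calls2), c("m01", "m02"))
  expect_equal(ev2$proportion_undistinguished, 0)
  # the empty panel distinguishes nothing
  ev3 <- evaluate_panel(gm, character(0))
  expect_equal(ev3$proportion_undistinguished, 1)
})

test_that("evaluation equals the brute-force pair oracle on random matrices", {
  set.seed(31)
  for (rep in 1:5) {
    calls <- matrix(sample(c(0L, 1L, 2L, NA), 12 * 30, replace = TRUE,
                           prob = c(.4, .05, .35, .2)), 30, 12)
    gm <- make_gm(calls)
    panel <- sample(gm$markers$marker_id, 12)
    ev <- evaluate_panel(gm, panel)
    orc <- oracle_evaluate(gm, panel)
    expect_equal(ev$proportion_undistinguished, orc$proportion)
    expect_equal(unname(ev$pair_counts), orc$counts)
    expect_equal(ev$min_mismatch, orc$min)
    expect_equal(ev$mean_mismatch, orc$mean)
  }
})

test_that("growing a panel never increases the undistinguished proportion", {
  set.seed(13)
  sim <- simulate_reference_panel(sim_config(n_lines = 10, n_markers = 60,
                                             seed = 8))
  ids <- sim$gm$markers$marker_id
  for (rep in 1:20) {
    small <- sample(ids, 5)
    big <- c(small, sample(setdiff(ids, small), 10))
    p_small <- evaluate_panel(sim$gm, small)$proportion_undistinguished
    p_big <- evaluate_panel(sim$gm, big)$proportion_undistinguished
    expect_lte(p_big, p_small)
  }
})

test_that("resampling optimization is deterministic and honours mandatory markers", {
  pl <- make_planted_id_panel()
  # the pair (00000, 10000) differs only at the first ID marker
  res1 <- optimize_panel(pl$gm, pl$gm$markers$marker_id, size = 6,
                         reps = 100, seed = 5)
  res2 <- optimize_panel(pl$gm, pl$gm$markers$marker_id, size = 6,
                         reps = 100, seed = 5)
  expect_identical(res1$panels[[1]]$markers, res2$panels[[1]]$markers)
  # every fully discriminating panel must contain every ID marker
  full <- res1$summary$proportion_undistinguished == 0
  for (i in which(full))
    expect_true(all(pl$id_markers %in% res1$panels[[i]]$markers))
  # mandatory markers are forced into every draw
  resm <- optimize_panel(pl$gm, pl$gm$markers$marker_id, size = 6,
                         reps = 20, mandatory = pl$id_markers[1:2], seed = 2)
  for (p in resm$panels)
    expect_true(all(pl$id_markers[1:2] %in% p$markers))
  expect_error(optimize_panel(pl$gm, pl$gm$markers$marker_id, size = 1,
                              reps = 5, mandatory = pl$id_markers[1:2]),
               "smaller than mandatory")
})

test_that("resampling matches exhaustive enumeration on a tiny instance", {
  set.seed(17)
  calls <- matrix(sample(c(0L, 2L), 8 * 7, replace = TRUE), 8, 7)
  gm <- make_gm(calls)
  cand <- gm$markers$marker_id
  orc <- oracle_best_subset(gm, cand, 4)        # C(8,4) = 70 subsets
  res <- optimize_panel(gm, cand, size = 4, reps = 1500, seed = 19)
  ev <- res$evaluations[[1]]
  expect_equal(ev$proportion_undistinguished, orc$proportion)
  expect_equal(ev$min_mismatch, orc$min)
  expect_equal(ev$mean_mismatch, orc$mean)
})

test_that("rapid panels are nested in the broad panel and find planted subsets", {
  pl <- make_planted_id_panel()
  broad <- panel_spec(pl$gm$markers$marker_id, name = "broad")
  res <- select_rapid_panel(pl$gm, broad, size = 5, reps = 800, seed = 23)
  expect_true(all(vapply(res$panels, function(p)
    all(p$markers %in% broad$markers), logical(1))))
  expect_setequal(res$panels[[1]]$markers, pl$id_markers)
  expect_equal(res$evaluations[[1]]$proportion_undistinguished, 0)
  # boundary: size equal to the broad panel returns the broad panel
  whole <- select_rapid_panel(pl$gm, broad, size = broad$size, reps = 3,
                              seed = 1)
  expect_setequal(whole$panels[[1]]$markers, broad$markers)
})

test_that("case-control allele scan matches the hand-computed chi-square", {
  # 10 case entries all hom major, 10 controls: construct allele counts
  # cases A=18, B=2; controls A=5, B=15
  case_calls <- c(rep(0L, 8), 1L, 1L)          # 18 major + 2 minor
  ctrl_calls <- c(rep(2L, 7), 1L, 0L, 0L)      # 5 major + 15 minor
  calls <- matrix(c(case_calls, ctrl_calls), 1)
  gm <- make_gm(calls)
  trait <- stats::setNames(rep(c(1, 0), each = 10), gm$entries)
  scan <- trait_marker_scan(gm, trait)
  expect_equal(round(scan$results$statistic, 2), 17.29)
  expect_lt(scan$results$p_value, 1e-4)
})

test_that("null and planted markers behave at the scan extremes", {
  set.seed(3)
  n <- 20
  background <- matrix(sample(c(0L, 2L), 10 * n, replace = TRUE), 10, n)
  planted <- c(rep(2L, 10), rep(0L, 10))       # perfectly concordant
  same_freq <- rep(c(0L, 2L), 10)              # identical in both classes
  gm <- make_gm(rbind(background, planted, same_freq))
  trait <- stats::setNames(rep(c(1, 0), each = 10), gm$entries)
  scan <- trait_marker_scan(gm, trait, trait_name = "qpm")
  expect_equal(scan$best, "m11")
  expect_equal(scan$results$statistic[12], 0)
  expect_equal(scan$results$p_value[12], 1)
  mono <- make_gm(matrix(0L, 1, n))
  s2 <- trait_marker_scan(mono, trait)
  expect_equal(s2$results$statistic, 0)
  expect_equal(s2$results$p_value, 1)
  expect_error(trait_marker_scan(gm, stats::setNames(rep(1, n), gm$entries)),
               "classes")
})

test_that("panel JSON round-trips markers, mandatory set, and name", {
  p <- panel_spec(c("a", "b", "c"), mandatory = "b", name = "broad80")
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_json(p, path, provenance = list(seed = 1, reps = 10))
  back <- read_panel_json(path)
  expect_equal(back$markers, p$markers)
  expect_equal(back$mandatory, p$mandatory)
  expect_equal(back$name, p$name)
  expect_error(panel_spec(c("a", "a")), "duplicated")
  expect_error(panel_spec("a", mandatory = "z"), "contained")
})
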