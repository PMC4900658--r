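# Marker filtering, PCA + K-means grouping, allocation strategies, uniform
# genomic spacing, panel discrimination evaluation, and replicated-resampling
# optimization of nested broad/rapid QC panels.

#' Filter thresholds for QC marker selection
#'
#' The default values are the stringent final selection rules used to build
#' a QC candidate panel: coverage between 2 and 15 reads per allele, missing
#' rate below 20%, heterogeneity below 6%, chromosome placement required.
#' An initial coarse screen would instead use `max_missing = 0.4`,
#' `min_maf = 0.05`, `max_het = 0.10` with no coverage or placement rule.
#'
#' @param max_missing Maximum missing-call fraction (markers strictly above
#'   are removed).
#' @param min_maf Minimum minor allele frequency.
#' @param max_het Maximum heterogeneity (HET fraction).
#' @param coverage_range Length-2 numeric `c(low, high)` of admissible mean
#'   reads per allele, or `NULL` for no coverage rule.
#' @param require_placed If `TRUE`, markers on chromosome `"0"` (unplaced)
#'   are removed.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_missing = 0.20, min_maf = 0,
                              max_het = 0.06, coverage_range = c(2, 15),
                              require_placed = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, max_het >= 0, max_het <= 1)
  if (!is.null(coverage_range)) {
    stopifnot(length(coverage_range) == 2,
              coverage_range[1] <= coverage_range[2])
  }
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 max_het = max_het, coverage_range = coverage_range,
                 require_placed = require_placed),
            class = "filter_thresholds")
}

#' Filter markers by informativeness thresholds
#'
#' A marker survives iff `missing_rate <= max_missing`, `maf >= min_maf`,
#' `het_rate <= max_het`, coverage falls inside `coverage_range` (when
#' given and available), and it is chromosome-placed when required. Markers
#' with undefined statistics (all calls missing) never survive.
#'
#' @param stats Marker statistics from [compute_marker_stats()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector of surviving marker ids, with attribute
#'   `"removed"`: a data frame naming the first rule that removed each
#'   casualty. Warns (not errors) when nothing survives.
#' @export
filter_markers <- function(stats, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  reason <- rep(NA_character_, nrow(stats))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  if (!is.null(stats$all_missing))
    reason <- flag(stats$all_missing, "all calls missing")
  reason <- flag(stats$missing_rate > thresholds$max_missing,
                 "missing rate above threshold")
  reason <- flag(stats$maf < thresholds$min_maf, "MAF below threshold")
  reason <- flag(stats$het_rate > thresholds$max_het,
                 "heterogeneity above threshold")
  if (!is.null(thresholds$coverage_range) && !all(is.na(stats$coverage))) {
    out_of_band <- stats$coverage < thresholds$coverage_range[1] |
      stats$coverage > thresholds$coverage_range[2]
    reason <- flag(!is.na(out_of_band) & out_of_band,
                   "coverage outside range")
  }
  if (thresholds$require_placed)
    reason <- flag(stats$chrom == "0", "no chromosome placement")
  keep <- is.na(reason)
  if (!any(keep)) warning("no markers survive the thresholds")
  survivors <- stats$marker_id[keep]
  attr(survivors, "removed") <-
    data.frame(marker_id = stats$marker_id[!keep],
               reason = reason[!keep], stringsAsFactors = FALSE)
  survivors
}

#' Group markers by PCA and K-means
#'
#' Markers are the observations and entries the variables: calls are coded
#' as minor-allele counts 0/1/2, missing calls mean-imputed per marker, and
#' the matrix centered (not scaled) before projection onto the leading
#' principal components ([stats::prcomp()]). [stats::kmeans()] with
#' multiple restarts partitions the component scores into `k` groups. Each
#' group's distance score is the mean Euclidean distance from its centroid
#' to the other group centroids, the weight used by the PGD allocation
#' strategy.
#'
#' @param gm A [genotype_matrix()].
#' @param candidate_ids Marker ids to group (default: all).
#' @param k Number of groups (default 5).
#' @param n_components Number of principal components retained (default 3).
#' @param seed Integer seed; grouping is deterministic given the seed.
#' @param nstart K-means restarts (>= 10 recommended).
#' @return A `marker_groups` list: `assignment` (named integer vector
#'   marker id -> group), `centroids` (k x n_components), `distance_score`
#'   (per-group mean centroid-to-other-centroids distance), `k`, `seed`.
#' @export
group_markers <- function(gm, candidate_ids = NULL, k = 5, n_components = 3,
                          seed = 1, nstart = 10) {
  if (is.null(candidate_ids)) candidate_ids <- gm$markers$marker_id
  gm <- subset_genotypes(gm, marker_ids = candidate_ids)
  if (k < 2) stop("k must be >= 2")
  if (length(candidate_ids) < k) stop("fewer candidate markers than groups")
  x <- gm$calls
  storage.mode(x) <- "double"
  for (i in seq_len(nrow(x))) {        # mean-impute missing per marker
    miss <- is.na(x[i, ])
    if (any(miss)) x[i, miss] <- mean(x[i, !miss])
  }
  if (anyNA(x)) stop("markers with all calls missing cannot be grouped")
  n_components <- min(n_components, ncol(x) - 1, nrow(x) - 1)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  if (nrow(unique(round(scores, 12))) < k)
    stop("fewer distinct marker profiles than groups")
  set.seed(seed)
  if (k == nrow(scores)) {  # degenerate partition: one marker per group
    cluster <- seq_len(k)
    centroids <- scores
    rownames(centroids) <- NULL
  } else {
    km <- stats::kmeans(scores, centers = k, nstart = max(nstart, 10),
                        iter.max = 100)
    cluster <- km$cluster
    centroids <- km$centers
  }
  dd <- as.matrix(stats::dist(centroids))
  score <- rowSums(dd) / (k - 1)
  assignment <- cluster
  names(assignment) <- candidate_ids
  structure(list(assignment = assignment, centroids = centroids,
                 distance_score = as.numeric(score), k = k, seed = seed),
            class = "marker_groups")
}

# Largest-remainder apportionment of `total` over non-negative weights,
# guaranteeing >= 1 per class when total >= number of classes.
largest_remainder <- function(weights, total, min_one = TRUE) {
  k <- length(weights)
  if (sum(weights) <= 0) weights <- rep(1, k)
  quota <- total * weights / sum(weights)
  counts <- floor(quota)
  rem <- quota - counts
  short <- total - sum(counts)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  if (min_one && total >= k && any(counts == 0)) {
    for (i in which(counts == 0)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1
      counts[i] <- 1
    }
  }
  as.integer(counts)
}

#' Allocate a marker selection across groups by strategy
#'
#' Divides a total selection among marker groups and samples markers
#' uniformly without replacement within each group:
#' \describe{
#'   \item{RANDOM}{no stratification — a simple random draw from all
#'     candidates.}
#'   \item{PG}{counts proportional to group sizes.}
#'   \item{NG}{equal counts per group.}
#'   \item{PGD}{counts proportional to each group's distance score (mean
#'     centroid-to-other-centroids distance).}
#' }
#' Counts use largest-remainder rounding, sum to `total`, and every group
#' receives at least one marker when `total >= k`. A group smaller than
#' its allocation forfeits the deficit to the group with the next-largest
#' remainder capacity; the reallocation is recorded in the result.
#'
#' @param groups A `marker_groups` object from [group_markers()].
#' @param total Total number of markers to select.
#' @param strategy `"RANDOM"`, `"PG"`, `"NG"` or `"PGD"`.
#' @param seed Integer seed for the within-group draws.
#' @return A list: `counts` (per group), `marker_ids` (sampled),
#'   `strategy`, `reallocated` (number of slots moved off full groups).
#' @export
allocate_by_strategy <- function(groups, total,
                                 strategy = c("RANDOM", "PG", "NG", "PGD"),
                                 seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(groups, "marker_groups"))
  ids <- names(groups$assignment)
  if (total > length(ids)) stop("total exceeds candidate marker count")
  set.seed(seed)
  if (strategy == "RANDOM") {
    picked <- sample(ids, total)
    return(list(counts = as.integer(table(factor(groups$assignment[picked],
                                                 levels = seq_len(groups$k)))),
                marker_ids = picked, strategy = strategy, reallocated = 0L))
  }
  k <- groups$k
  sizes <- as.integer(table(factor(groups$assignment, levels = seq_len(k))))
  weights <- switch(strategy,
    PG = sizes,
    NG = rep(1, k),
    PGD = groups$distance_score
  )
  counts <- largest_remainder(weights, total)
  # cap at group sizes, pushing any deficit to groups with spare capacity
  reallocated <- 0L
  repeat {
    over <- counts > sizes
    if (!any(over)) break
    deficit <- sum(counts[over] - sizes[over])
    reallocated <- reallocated + deficit
    counts[over] <- sizes[over]
    spare <- sizes - counts
    if (sum(spare) < deficit) stop("total exceeds candidate marker count")
    add <- largest_remainder(ifelse(spare > 0, weights, 0), deficit,
                             min_one = FALSE)
    counts <- counts + pmin(add, spare)
    deficit <- total - sum(counts)
    if (deficit > 0) {  # rounding pushed some addition onto full groups
      for (g in order(spare, decreasing = TRUE)) {
        if (deficit == 0) break
        room <- sizes[g] - counts[g]
        take <- min(room, deficit)
        counts[g] <- counts[g] + take
        deficit <- deficit - take
      }
    }
  }
  picked <- unlist(lapply(seq_len(k), function(g) {
    pool <- ids[groups$assignment == g]
    if (counts[g] == 0) character(0)
    else if (length(pool) == 1 && counts[g] == 1) pool
    else sample(pool, counts[g])
  }))
  list(counts = counts, marker_ids = picked, strategy = strategy,
       reallocated = reallocated)
}

#' Select markers on a uniform genomic grid
#'
#' Apportions a per-chromosome quota proportional to chromosome length
#' (largest remainder), divides each chromosome into that many equal-width
#' bins, and picks from each bin the marker nearest the bin midpoint (ties
#' to the lower position). An empty bin forfeits its slot to the nearest
#' bin on the same chromosome that still holds unselected markers.
#'
#' @param markers Data frame with `marker_id`, `chrom`, `pos`; all markers
#'   must be placed (`chrom != "0"`).
#' @param total Number of markers to select (<= number of markers).
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   in bp; defaults to the maximum marker position per chromosome.
#' @return Character vector of selected marker ids, ordered by chromosome
#'   and position.
#' @export
select_uniform_genomic <- function(markers, total, chrom_lengths = NULL) {
  if (any(markers$chrom == "0"))
    stop("all markers must be chromosome-placed (chrom != \"0\")")
  if (total > nrow(markers)) stop("total exceeds placed marker count")
  chroms <- unique(markers$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(markers$pos[markers$chrom == ch]), numeric(1))
  }
  chrom_lengths <- chrom_lengths[chroms]
  quotas <- largest_remainder(chrom_lengths, total, min_one = FALSE)
  # chromosomes with fewer markers than quota forfeit to the others
  n_per <- vapply(chroms, function(ch) sum(markers$chrom == ch), integer(1))
  while (any(quotas > n_per)) {
    over <- quotas > n_per
    excess <- sum(quotas[over] - n_per[over])
    quotas[over] <- n_per[over]
    room <- n_per - quotas
    for (g in order(chrom_lengths, decreasing = TRUE)) {
      if (excess == 0) break
      take <- min(room[g], excess)
      quotas[g] <- quotas[g] + take
      excess <- excess - take
    }
  }
  selected <- character(0)
  for (ci in seq_along(chroms)) {
    q <- quotas[ci]
    if (q == 0) next
    sub <- markers[markers$chrom == chroms[ci], , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    width <- chrom_lengths[ci] / q
    bin_of <- pmin(pmax(ceiling(sub$pos / width), 1), q)
    taken <- logical(nrow(sub))
    pick_from <- function(pool_idx, midpoint) {
      pool_idx[order(abs(sub$pos[pool_idx] - midpoint),
                     sub$pos[pool_idx])][1]
    }
    order_bins <- seq_len(q)
    pending <- integer(0)
    for (b in order_bins) {
      pool <- which(bin_of == b & !taken)
      if (length(pool) == 0) { pending <- c(pending, b); next }
      taken[pick_from(pool, (b - 0.5) * width)] <- TRUE
    }
    for (b in pending) {  # forfeit to nearest bin with unselected markers
      avail_bins <- unique(bin_of[!taken])
      if (length(avail_bins) == 0) break
      nb <- avail_bins[order(abs(avail_bins - b), avail_bins)][1]
      pool <- which(bin_of == nb & !taken)
      taken[pick_from(pool, (nb - 0.5) * width)] <- TRUE
    }
    selected <- c(selected, sub$marker_id[taken])
  }
  selected
}

#' Define a QC marker panel
#'
#' @param marker_ids Ordered character vector of marker ids (no
#'   duplicates).
#' @param mandatory Marker ids that must be present (e.g. trait-specific
#'   markers); must be a subset of `marker_ids`.
#' @param name Optional panel name.
#' @return A `panel_spec` list with `markers`, `mandatory`, `size`, `name`.
#' @export
panel_spec <- function(marker_ids, mandatory = character(0), name = NULL) {
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids in panel")
  if (!all(mandatory %in% marker_ids))
    stop("mandatory markers must be contained in the panel")
  structure(list(markers = marker_ids, mandatory = as.character(mandatory),
                 size = length(marker_ids), name = name),
            class = "panel_spec")
}

#' Evaluate a panel's power to distinguish entries
#'
#' For each unordered pair of entries, counts the panel markers that are
#' jointly non-missing and carry differing calls. A pair is
#' *undistinguished* when that count is zero — including pairs with no
#' jointly non-missing panel marker, a deliberately conservative reading
#' for QC.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [panel_spec()] or character vector of marker ids. An
#'   empty panel is allowed and leaves every pair undistinguished.
#' @return A `panel_evaluation` list: `proportion_undistinguished`,
#'   `undistinguished_pairs` (two-column matrix of labels), `pair_counts`
#'   (per-pair mismatch counts, named `a|b`), `min_mismatch`,
#'   `mean_mismatch`, `n_pairs`.
#' @export
evaluate_panel <- function(gm, panel) {
  ids <- if (inherits(panel, "panel_spec")) panel$markers else
    as.character(panel)
  n <- length(gm$entries)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs == 0) stop("need at least 2 entries")
  if (length(ids) == 0) {
    counts <- integer(n_pairs)
  } else {
    calls <- subset_genotypes(gm, marker_ids = ids)$calls
    counts <- integer(n_pairs)
    p <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p <- p + 1L
        counts[p] <- sum(calls[, i] != calls[, j], na.rm = TRUE)
      }
    }
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  labels <- cbind(gm$entries[pairs[, 1]], gm$entries[pairs[, 2]])
  names(counts) <- paste(labels[, 1], labels[, 2], sep = "|")
  und <- counts == 0
  structure(list(
    proportion_undistinguished = mean(und),
    undistinguished_pairs = labels[und, , drop = FALSE],
    pair_counts = counts,
    min_mismatch = min(counts),
    mean_mismatch = mean(counts),
    n_pairs = n_pairs
  ), class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf(
    "panel evaluation: %.4f of %d pairs undistinguished; mismatches min %d, mean %.2f\n",
    x$proportion_undistinguished, x$n_pairs, x$min_mismatch, x$mean_mismatch))
  invisible(x)
}

# Ranking order over evaluations: fully discriminating panels first, by
# (max min-mismatch, max mean-mismatch, draw order); otherwise ascending
# undistinguished proportion then the same keys.
rank_evaluations <- function(evals) {
  prop <- vapply(evals, `[[`, numeric(1), "proportion_undistinguished")
  minm <- vapply(evals, `[[`, numeric(1), "min_mismatch")
  meanm <- vapply(evals, `[[`, numeric(1), "mean_mismatch")
  order(prop, -minm, -meanm, seq_along(evals))
}

#' Optimize a QC panel by replicated random resampling
#'
#' Draws `reps` random subsets of the requested size from the candidate
#' markers, always including the mandatory markers, evaluates each with
#' [evaluate_panel()], and ranks them: subsets distinguishing every entry
#' pair come first, ordered by largest minimum pairwise mismatch count,
#' then largest mean; if none reaches full discrimination, by ascending
#' undistinguished proportion and the same keys. Deterministic under
#' `seed`.
#'
#' @param gm A `genotype_matrix`.
#' @param candidates Character vector of candidate marker ids.
#' @param size Panel size (`|mandatory| <= size <= |candidates|`).
#' @param reps Number of random subsets to draw.
#' @param mandatory Marker ids forced into every subset.
#' @param seed Integer seed.
#' @param n_top Number of top-ranked panels to return (default 5).
#' @return A `panel_search` list: `panels` (list of [panel_spec()]s in rank
#'   order), `evaluations` (matching list), `summary` (data frame of rank,
#'   proportion undistinguished, min/mean mismatch, draw index), and the
#'   search parameters.
#' @export
optimize_panel <- function(gm, candidates, size, reps = 2000,
                           mandatory = character(0), seed = 1, n_top = 5) {
  candidates <- as.character(candidates)
  if (!all(mandatory %in% candidates))
    stop("mandatory markers must be among the candidates")
  if (size < length(mandatory)) stop("size smaller than mandatory set")
  if (size > length(candidates)) stop("size exceeds candidate count")
  if (reps < 1) stop("reps must be >= 1")
  free <- setdiff(candidates, mandatory)
  n_free <- size - length(mandatory)
  set.seed(seed)
  panels <- vector("list", reps)
  evals <- vector("list", reps)
  for (r in seq_len(reps)) {
    extra <- if (n_free == 0) character(0)
             else if (length(free) == 1) free
             else sample(free, n_free)
    ids <- c(mandatory, extra)
    panels[[r]] <- panel_spec(ids, mandatory = mandatory,
                              name = sprintf("draw%04d", r))
    evals[[r]] <- evaluate_panel(gm, ids)
  }
  ord <- rank_evaluations(evals)
  top <- ord[seq_len(min(n_top, reps))]
  summary <- data.frame(
    rank = seq_along(top),
    name = vapply(panels[top], `[[`, character(1), "name"),
    proportion_undistinguished = vapply(evals[top], `[[`, numeric(1),
                                        "proportion_undistinguished"),
    min_mismatch = vapply(evals[top], `[[`, numeric(1), "min_mismatch"),
    mean_mismatch = vapply(evals[top], `[[`, numeric(1), "mean_mismatch"),
    draw = top,
    stringsAsFactors = FALSE
  )
  structure(list(panels = panels[top], evaluations = evals[top],
                 summary = summary, size = size, reps = reps, seed = seed,
                 mandatory = mandatory),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("panel search: size %d, %d resampling reps\n", x$size, x$reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select a rapid QC panel nested within a broad panel
#'
#' Runs the same replicated-resampling optimization as [optimize_panel()]
#' with the broad panel as the candidate pool, so every returned rapid
#' panel is nested inside the broad one by construction.
#'
#' @param gm A `genotype_matrix`.
#' @param broad A [panel_spec()] (the broad QC panel).
#' @param size Rapid panel size (< broad size... equal returns the broad
#'   panel itself).
#' @inheritParams optimize_panel
#' @return A `panel_search`, as [optimize_panel()].
#' @export
select_rapid_panel <- function(gm, broad, size, reps = 2000,
                               mandatory = character(0), seed = 1,
                               n_top = 5) {
  stopifnot(inherits(broad, "panel_spec"))
  optimize_panel(gm, candidates = broad$markers, size = size, reps = reps,
                 mandatory = mandatory, seed = seed, n_top = n_top)
}

#' Case-control allele association scan for trait-specific markers
#'
#' For a binary trait over entries, builds per marker the 2x2 allele-count
#' table (trait class x allele, homozygotes contributing two copies and
#' heterozygotes one of each) and computes the Pearson chi-square statistic
#' without continuity correction (1 df), with the p-value from the upper
#' tail. Markers monomorphic overall, or with an empty allele margin, get
#' statistic 0 and p-value 1. The best marker minimises the p-value (ties
#' broken by larger statistic, then marker order).
#'
#' @param gm A `genotype_matrix`.
#' @param trait Named vector of 0/1 trait values; names are entry labels
#'   present in `gm`. Both classes must be non-empty.
#' @param trait_name Label recorded in the result.
#' @return A list: `results` (data frame marker_id, statistic, p_value,
#'   trait) and `best` (the best marker id).
#' @export
trait_marker_scan <- function(gm, trait, trait_name = "trait") {
  trait <- trait[!is.na(trait)]
  if (!all(trait %in% c(0, 1))) stop("trait values must be 0/1")
  idx <- match(names(trait), gm$entries)
  if (anyNA(idx)) stop("trait entries absent from matrix: ",
                       paste(names(trait)[is.na(idx)], collapse = ", "))
  if (length(unique(trait)) < 2) stop("both trait classes must be non-empty")
  calls <- gm$calls[, idx, drop = FALSE]
  case <- trait == 1
  stat <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    # allele counts: minor = code, major = 2 - code, over non-missing
    a_case <- sum(2 - row[case], na.rm = TRUE)   # major alleles, cases
    b_case <- sum(row[case], na.rm = TRUE)       # minor alleles, cases
    a_ctrl <- sum(2 - row[!case], na.rm = TRUE)
    b_ctrl <- sum(row[!case], na.rm = TRUE)
    tab <- matrix(c(a_case, b_case, a_ctrl, b_ctrl), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stat[i] <- 0
    } else {
      stat[i] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic)
    }
  }
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[stat == 0] <- 1
  results <- data.frame(marker_id = gm$markers$marker_id,
                        statistic = stat, p_value = p,
                        trait = trait_name, stringsAsFactors = FALSE)
  best <- results$marker_id[order(results$p_value, -results$statistic,
                                  seq_len(nrow(results)))][1]
  list(results = results, best = best)
}

#' Write a panel specification as JSON
#'
#' @param panel A [panel_spec()].
#' @param path Output path.
#' @param provenance Optional list (seed, reps, rules) recorded alongside.
#' @return The path, invisibly.
#' @export
write_panel_json <- function(panel, path, provenance = NULL) {
  obj <- list(name = panel$name, markers = panel$markers,
              mandatory = panel$mandatory, size = panel$size,
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a panel specification from JSON
#'
#' @param path Path to a JSON file written by [write_panel_json()].
#' @return A [panel_spec()].
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_spec(obj$markers, mandatory = obj$mandatory %||% character(0),
             name = obj$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
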