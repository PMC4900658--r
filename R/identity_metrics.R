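# Pairwise allele-sharing distance, blind-test similarity, complete-linkage
# clustering and principal coordinate embedding of entries.
#
# With calls coded as minor-allele counts, two unordered diploid genotypes
# at one locus share 2 - |a - b| alleles, so the per-locus allele-sharing
# distance is simply |a - b| and lies in {0, 1, 2}.

#' Alleles shared by two diploid calls at one locus
#'
#' Counts matched alleles between two unordered genotypes: identical
#' homozygotes share 2, a homozygote and a heterozygote share 1, opposite
#' homozygotes share 0, two heterozygotes share 2.
#'
#' @param call_a,call_b Integer call codes (0, 1, 2); missing calls are an
#'   error — loci with missing data are excluded upstream.
#' @return Integer vector of shared-allele counts in \{0, 1, 2\}.
#' @export
shared_alleles <- function(call_a, call_b) {
  if (anyNA(call_a) || anyNA(call_b))
    stop("missing call: exclude jointly missing loci before counting")
  2L - abs(as.integer(call_a) - as.integer(call_b))
}

#' Allele-sharing distance matrix between entries
#'
#' For each unordered pair of entries, averages the per-locus distance
#' `2 - shared alleles` over the markers at which both entries have calls.
#' The distance ranges from 0 (identical genotypes) to 2 (opposite
#' homozygotes at every usable marker). Pairs with no jointly non-missing
#' marker are `NA` — left undefined rather than silently assigned either
#' extreme.
#'
#' @param gm A [genotype_matrix()] with at least two entries.
#' @return An object of class `sharing_dist`: a list with `d` (symmetric
#'   distance matrix, entries as dimnames), `n_markers` (per-pair count of
#'   jointly non-missing markers) and `entries`.
#' @export
allele_sharing_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$entries)
  if (n < 2) stop("need at least 2 entries")
  calls <- gm$calls
  d <- matrix(0, n, n, dimnames = list(gm$entries, gm$entries))
  cnt <- matrix(0L, n, n, dimnames = list(gm$entries, gm$entries))
  diag(cnt) <- colSums(!is.na(calls))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !is.na(calls[, i]) & !is.na(calls[, j])
      m <- sum(use)
      cnt[i, j] <- cnt[j, i] <- m
      dij <- if (m == 0) NA_real_
             else mean(abs(calls[use, i] - calls[use, j]))
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(list(d = d, n_markers = cnt, entries = gm$entries),
            class = "sharing_dist")
}

#' @export
print.sharing_dist <- function(x, ...) {
  cat(sprintf("allele-sharing distances for %d entries\n", length(x$entries)))
  print(round(x$d, 4))
  invisible(x)
}

#' Identity-by-state similarity between two entries
#'
#' Blind-test similarity: the number of identical alleles divided by the
#' number of non-missing alleles compared, over an optional marker panel.
#' Equals `1 - d/2` for the allele-sharing distance `d` computed on the
#' same marker set.
#'
#' @param gm A `genotype_matrix`.
#' @param entry_a,entry_b Entry labels.
#' @param panel Optional character vector of marker ids restricting the
#'   comparison (a QC panel); `NULL` uses all markers.
#' @return A list: `similarity` in \[0, 1\], `n_markers` used, and the two
#'   labels. Errors when no jointly non-missing marker exists.
#' @export
similarity <- function(gm, entry_a, entry_b, panel = NULL) {
  if (!is.null(panel)) gm <- subset_genotypes(gm, marker_ids = panel)
  ia <- match(entry_a, gm$entries)
  ib <- match(entry_b, gm$entries)
  if (is.na(ia) || is.na(ib)) stop("unknown entry label")
  a <- gm$calls[, ia]
  b <- gm$calls[, ib]
  use <- !is.na(a) & !is.na(b)
  if (!any(use)) stop("no jointly non-missing markers for ",
                      entry_a, " vs ", entry_b)
  shared <- sum(shared_alleles(a[use], b[use]))
  list(entry_a = entry_a, entry_b = entry_b,
       similarity = shared / (2 * sum(use)),
       n_markers = sum(use))
}

#' Complete-linkage tree of entries in Newick form
#'
#' Agglomerates entries by complete linkage on the allele-sharing distances
#' (via [stats::hclust()]) and emits a Newick string with branch lengths
#' equal to parent merge height minus child merge height (leaves at height
#' 0). Children at each node are ordered by their lexicographically
#' smallest leaf label, so the output is invariant to input order.
#'
#' @param dm A `sharing_dist` from [allele_sharing_distance()].
#' @return A single Newick string (terminated by `;`).
#' @export
cluster_tree <- function(dm) {
  stopifnot(inherits(dm, "sharing_dist"))
  if (anyNA(dm$d))
    stop("undefined entry pairs (no shared markers): expand the marker set")
  hc <- stats::hclust(stats::as.dist(dm$d), method = "complete")
  newick_from_hclust(hc)
}

# Deterministic hclust -> Newick: branch length = parent height - child
# height; child order by smallest leaf label.
newick_from_hclust <- function(hc) {
  labels <- hc$labels
  node_text <- function(idx, parent_height) {
    if (idx < 0) {  # leaf (hclust convention: negative = observation)
      lab <- labels[-idx]
      list(text = sprintf("%s:%.10g", lab, parent_height), min_leaf = lab)
    } else {
      h <- hc$height[idx]
      kids <- lapply(hc$merge[idx, ], node_text, parent_height = h)
      kids <- kids[order(vapply(kids, `[[`, character(1), "min_leaf"))]
      list(text = sprintf("(%s):%.10g",
                          paste(vapply(kids, `[[`, character(1), "text"),
                                collapse = ","),
                          parent_height - h),
           min_leaf = kids[[1]]$min_leaf)
    }
  }
  root <- node_text(nrow(hc$merge), hc$height[nrow(hc$merge)])
  # strip the root's zero-length stem
  sub(":[^:()]*$", ";", root$text)
}

#' Principal coordinate analysis of entries
#'
#' Classical metric multidimensional scaling (via [stats::cmdscale()]) of
#' the allele-sharing distance matrix: entries are embedded so that
#' Euclidean distances approximate the input distances, axes ordered by
#' decreasing eigenvalue.
#'
#' @param dm A `sharing_dist`.
#' @param n_axes Number of coordinate axes to return (< number of entries).
#' @return A list: `coordinates` (entries x axes matrix), `eigenvalues`
#'   (all of them, descending), and `negative_warning` (`TRUE` when
#'   negative-eigenvalue mass exceeds the retained positive mass,
#'   indicating a poorly Euclidean-embeddable distance).
#' @export
pcoa <- function(dm, n_axes = 2) {
  stopifnot(inherits(dm, "sharing_dist"))
  if (anyNA(dm$d))
    stop("undefined entry pairs (no shared markers): expand the marker set")
  n <- length(dm$entries)
  if (n_axes >= n) stop("n_axes must be smaller than the number of entries")
  # cmdscale warns when it drops null axes; we pad those with zeros below
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm$d), k = n_axes, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < n_axes) {  # cmdscale drops null axes; pad with zeros
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  }
  rownames(coords) <- dm$entries
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  eig <- fit$eig
  neg_mass <- sum(abs(eig[eig < 0]))
  pos_mass <- sum(pmax(eig[seq_len(n_axes)], 0))
  list(coordinates = coords, eigenvalues = eig,
       negative_warning = neg_mass > pos_mass)
}

#' Write a distance matrix as square TSV
#'
#' @param dm A `sharing_dist`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write PCoA coordinates as TSV
#'
#' @param fit Result of [pcoa()].
#' @param path Output path.
#' @param groups Optional character vector of categorical labels per entry,
#'   written as a final column for generic 3-D viewers.
#' @return The path, invisibly.
#' @export
write_pcoa <- function(fit, path, groups = NULL) {
  df <- data.frame(entry = rownames(fit$coordinates), fit$coordinates,
                   check.names = FALSE)
  if (!is.null(groups)) df$group <- groups
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
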