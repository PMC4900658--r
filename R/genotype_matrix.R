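# Core container: diploid SNP calls for a collection of inbred entries.
#
# Calls are stored as an integer matrix (markers x entries) coding the count
# of the marker's minor allele: 0 = homozygous major, 1 = heterozygous,
# 2 = homozygous minor, NA = missing. All downstream statistics are
# allele-label-agnostic, so the major/minor orientation (assigned at load by
# frequency, ties broken alphabetically) carries no information loss.

CALL_HOM_MAJOR <- 0L
CALL_HET <- 1L
CALL_HOM_MINOR <- 2L

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a genotype matrix
#'
#' Bundles diploid SNP calls with marker metadata into a validated
#' `genotype_matrix` object, the substrate for all panel-QC statistics.
#'
#' @param calls Integer matrix, markers in rows and entries in columns, with
#'   values 0 (homozygous major allele), 1 (heterozygous), 2 (homozygous
#'   minor allele) or `NA` (missing).
#' @param markers Data frame with columns `marker_id` (unique), `chrom`
#'   (character; `"0"` denotes an unplaced marker), `pos` (1-based bp
#'   position), `allele_major` and `allele_minor` (single bases, distinct).
#' @param entries Character vector of unique entry labels, one per column.
#' @param depth Optional numeric vector of mean sequencing reads per allele,
#'   one finite non-negative value per marker.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `markers`, `entries` and `depth`.
#' @export
genotype_matrix <- function(calls, markers, entries, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  entries <- as.character(entries)
  gm <- structure(
    list(calls = calls, markers = markers, entries = entries, depth = depth),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  dimnames(gm$calls) <- list(markers$marker_id, entries)
  gm
}

validate_genotype_matrix <- function(gm) {
  m <- gm$markers
  required <- c("marker_id", "chrom", "pos", "allele_major", "allele_minor")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0)
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(m) == 0) stop("genotype matrix has zero markers")
  if (length(gm$entries) == 0) stop("genotype matrix has zero entries")
  if (anyDuplicated(m$marker_id))
    stop("duplicated marker_id: ",
         paste(unique(m$marker_id[duplicated(m$marker_id)]), collapse = ", "))
  if (anyDuplicated(gm$entries))
    stop("duplicated entry label: ",
         paste(unique(gm$entries[duplicated(gm$entries)]), collapse = ", "))
  if (!all(dim(gm$calls) == c(nrow(m), length(gm$entries))))
    stop("calls must be an n_markers x n_entries matrix")
  bad <- !(gm$calls %in% c(0L, 1L, 2L)) & !is.na(gm$calls)
  if (any(bad)) stop("calls contain values outside {0, 1, 2, NA}")
  if (!all(m$allele_major %in% VALID_BASES) ||
      !all(m$allele_minor %in% VALID_BASES))
    stop("alleles must be single bases in {A, C, G, T}")
  if (any(m$allele_major == m$allele_minor))
    stop("major and minor alleles must differ")
  placed <- m$chrom != "0"
  if (any(placed & (is.na(m$pos) | m$pos < 1)))
    stop("placed markers require a 1-based position >= 1")
  if (!is.null(gm$depth)) {
    if (length(gm$depth) != nrow(m))
      stop("depth must have one value per marker")
    if (any(!is.finite(gm$depth)) || any(gm$depth < 0))
      stop("depth values must be finite and non-negative")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d entries\n",
              nrow(x$calls), length(x$entries)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$markers$chrom)), collapse = " ")))
  n <- length(x$calls)
  cat(sprintf("  missing: %.1f%%  het: %.1f%%  depth: %s\n",
              100 * sum(is.na(x$calls)) / n,
              100 * sum(x$calls == CALL_HET, na.rm = TRUE) / n,
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by markers and/or entries
#'
#' Slices calls, marker metadata and depth consistently, preserving the
#' order of the request.
#'
#' @param gm A `genotype_matrix`.
#' @param marker_ids Optional character vector of marker ids to keep, in the
#'   order requested. `NULL` keeps all markers.
#' @param entry_labels Optional character vector of entry labels to keep.
#'   `NULL` keeps all entries.
#'
#' @return A `genotype_matrix` restricted to the requested axes.
#' @export
subset_genotypes <- function(gm, marker_ids = NULL, entry_labels = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mi <- seq_len(nrow(gm$calls))
  if (!is.null(marker_ids)) {
    mi <- match(marker_ids, gm$markers$marker_id)
    if (anyNA(mi))
      stop("unknown marker id(s): ",
           paste(marker_ids[is.na(mi)], collapse = ", "))
  }
  ei <- seq_along(gm$entries)
  if (!is.null(entry_labels)) {
    ei <- match(entry_labels, gm$entries)
    if (anyNA(ei))
      stop("unknown entry label(s): ",
           paste(entry_labels[is.na(ei)], collapse = ", "))
  }
  genotype_matrix(
    calls = gm$calls[mi, ei, drop = FALSE],
    markers = gm$markers[mi, , drop = FALSE],
    entries = gm$entries[ei],
    depth = if (is.null(gm$depth)) NULL else gm$depth[mi]
  )
}
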