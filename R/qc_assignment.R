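# Blind-test identity assignment against a reference collection,
# heterogeneity flags, and per-entry off-type counting with pass/fail.

# Accept a query profile as a named integer vector of call codes or as a
# one-entry genotype_matrix; return codes named by marker id.
as_profile <- function(profile) {
  if (inherits(profile, "genotype_matrix")) {
    if (length(profile$entries) != 1)
      stop("query matrix must hold exactly one entry")
    codes <- profile$calls[, 1]
    names(codes) <- profile$markers$marker_id
    return(codes)
  }
  if (is.null(names(profile))) stop("profile must be named by marker id")
  codes <- as.integer(profile)
  names(codes) <- names(profile)
  codes
}

#' Assign a query genotype to its most similar reference entry
#'
#' The blind test: computes identity-by-state similarity (shared alleles
#' over non-missing alleles, see [similarity()]) between the query profile
#' and every reference entry on the QC panel, and ranks references by
#' descending similarity. When an expected label is supplied the verdict is
#' `MATCH` if it tops the ranking and `MISLABELED` otherwise; a tie between
#' the top two similarities (within 1e-9) yields `AMBIGUOUS`. Reference
#' entries sharing no non-missing panel marker with the query are dropped
#' with a warning.
#'
#' @param query A named vector of call codes (marker id -> 0/1/2/NA) or a
#'   one-entry [genotype_matrix()].
#' @param reference A `genotype_matrix` of reference entries.
#' @param panel A [panel_spec()] or character vector of marker ids; `NULL`
#'   uses every marker shared between query and reference.
#' @param expected Optional label the query is believed to be.
#' @return An `identity_assignment` list: `query` (expected label or
#'   `NA`), `ranking` (data frame reference, similarity, n_markers in
#'   descending similarity), `best`, `best_similarity`, `verdict`.
#' @export
assign_identity <- function(query, reference, panel = NULL, expected = NULL) {
  codes <- as_profile(query)
  ids <- if (is.null(panel)) intersect(names(codes),
                                       reference$markers$marker_id)
         else if (inherits(panel, "panel_spec")) panel$markers
         else as.character(panel)
  missing_in_query <- setdiff(ids, names(codes))
  if (length(missing_in_query) > 0)
    stop("query lacks panel marker(s): ",
         paste(utils::head(missing_in_query, 5), collapse = ", "))
  ref <- subset_genotypes(reference, marker_ids = ids)
  q <- codes[ids]
  if (all(is.na(q))) stop("query has no non-missing calls on the panel")
  sims <- rep(NA_real_, length(ref$entries))
  used <- integer(length(ref$entries))
  for (i in seq_along(ref$entries)) {
    r <- ref$calls[, i]
    ok <- !is.na(q) & !is.na(r)
    used[i] <- sum(ok)
    if (used[i] > 0)
      sims[i] <- sum(shared_alleles(q[ok], r[ok])) / (2 * used[i])
  }
  if (anyNA(sims)) {
    warning("reference entries dropped (no shared panel markers): ",
            paste(ref$entries[is.na(sims)], collapse = ", "))
  }
  keep <- !is.na(sims)
  ranking <- data.frame(reference = ref$entries[keep],
                        similarity = sims[keep], n_markers = used[keep],
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$similarity, ranking$reference), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  best <- ranking$reference[1]
  tie <- nrow(ranking) > 1 &&
    abs(ranking$similarity[1] - ranking$similarity[2]) <= 1e-9
  verdict <- if (tie) "AMBIGUOUS"
             else if (is.null(expected) || expected == best) "MATCH"
             else "MISLABELED"
  structure(list(query = if (is.null(expected)) NA_character_ else expected,
                 ranking = ranking, best = best,
                 best_similarity = ranking$similarity[1],
                 verdict = verdict),
            class = "identity_assignment")
}

#' @export
print.identity_assignment <- function(x, ...) {
  cat(sprintf("blind test: best match %s (similarity %.4f) -> %s\n",
              x$best, x$best_similarity, x$verdict))
  print(utils::head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' Heterogeneity of a sample profile on a panel
#'
#' Residual non-fixation: the fraction of heterozygous calls among
#' non-missing calls on the panel. An inbred line profile above the
#' threshold is flagged for purification or retesting.
#'
#' @param profile Named call codes or a one-entry `genotype_matrix`.
#' @param panel Marker ids or a [panel_spec()]; `NULL` uses all profile
#'   markers.
#' @param threshold Flag when the rate strictly exceeds this fraction
#'   (default 0.10, a coarse-screen ceiling for inbred lines).
#' @return A list: `het_rate`, `n_calls` (non-missing), `flagged`.
#' @export
heterogeneity_check <- function(profile, panel = NULL, threshold = 0.10) {
  codes <- as_profile(profile)
  if (!is.null(panel)) {
    ids <- if (inherits(panel, "panel_spec")) panel$markers else panel
    codes <- codes[intersect(ids, names(codes))]
  }
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) stop("no non-missing calls on the panel")
  rate <- mean(codes == CALL_HET)
  list(het_rate = rate, n_calls = length(codes), flagged = rate > threshold)
}

#' Count off-type individuals within an entry and apply the QC threshold
#'
#' Compares each genotyped individual of an entry to the entry's reference
#' profile on the panel. An individual is an off-type when its number of
#' jointly non-missing, mismatching panel calls exceeds
#' `mismatch_tolerance` (default 1, absorbing a single genotyping error on
#' a small rapid panel). The entry passes QC when the off-type count is at
#' most `threshold` (default 2 per entry); otherwise it should be retested
#' and, on a second failure, regenerated from a different seed source.
#'
#' @param individuals Matrix of call codes, panel markers x individuals
#'   (rownames marker ids, colnames individual labels), or a
#'   `genotype_matrix`.
#' @param reference Named call codes (or one-entry `genotype_matrix`) for
#'   the entry's reference profile.
#' @param panel Marker ids or [panel_spec()]; `NULL` uses all shared
#'   markers.
#' @param mismatch_tolerance Mismatching calls allowed per individual
#'   before it is called an off-type.
#' @param threshold Maximum off-types for the entry to pass.
#' @param entry Entry label recorded in the report.
#' @return An `entry_purity` list: `entry`, `n` (individuals scored), `k`
#'   (off-types), `off_type_individuals`, `excluded` (individuals with no
#'   usable panel call), `het_rate` (of the pooled individuals), `pass`,
#'   `threshold`, `mismatch_tolerance`, `mismatch_counts`.
#' @export
count_off_types <- function(individuals, reference, panel = NULL,
                            mismatch_tolerance = 1, threshold = 2,
                            entry = "entry") {
  if (inherits(individuals, "genotype_matrix")) {
    mat <- individuals$calls
    rownames(mat) <- individuals$markers$marker_id
  } else {
    mat <- as.matrix(individuals)
    if (is.null(rownames(mat))) stop("individuals need marker id rownames")
  }
  ref <- as_profile(reference)
  ids <- if (is.null(panel)) intersect(rownames(mat), names(ref))
         else if (inherits(panel, "panel_spec")) panel$markers
         else as.character(panel)
  if (!all(ids %in% rownames(mat)) || !all(ids %in% names(ref)))
    stop("panel markers absent from individuals or reference")
  mat <- mat[ids, , drop = FALSE]
  ref <- ref[ids]
  if (is.null(colnames(mat))) colnames(mat) <- paste0("ind", seq_len(ncol(mat)))
  usable <- colSums(!is.na(mat) & !is.na(ref)) > 0
  mism <- vapply(seq_len(ncol(mat)), function(j)
    sum(mat[, j] != ref, na.rm = TRUE), integer(1))
  names(mism) <- colnames(mat)
  off <- usable & mism > mismatch_tolerance
  k <- sum(off)
  het_rate <- mean(mat[!is.na(mat)] == CALL_HET)
  structure(list(entry = entry, n = sum(usable), k = k,
                 off_type_individuals = colnames(mat)[off],
                 excluded = colnames(mat)[!usable],
                 het_rate = het_rate, pass = k <= threshold,
                 threshold = threshold,
                 mismatch_tolerance = mismatch_tolerance,
                 mismatch_counts = mism[usable]),
            class = "entry_purity")
}

#' @export
print.entry_purity <- function(x, ...) {
  cat(sprintf("entry %s: %d/%d off-types (threshold %d) -> %s\n",
              x$entry, x$k, x$n, x$threshold,
              if (x$pass) "PASS" else "FAIL (retest)"))
  invisible(x)
}
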