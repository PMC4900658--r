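# Shared fixtures and independent brute-force oracles for the test suite.
# Fixtures are built in code; oracles deliberately recount call-by-call and
# never reuse the implementation under test.

# A small genotype matrix from a plain matrix of call codes.
make_gm <- function(calls, chrom = NULL, pos = NULL, depth = NULL,
                    alleles = c("A", "G")) {
  calls <- as.matrix(calls)
  nm <- nrow(calls)
  genotype_matrix(
    calls,
    markers = data.frame(
      marker_id = sprintf("m%02d", seq_len(nm)),
      chrom = if (is.null(chrom)) rep("1", nm) else chrom,
      pos = if (is.null(pos)) seq_len(nm) * 1000L else as.integer(pos),
      allele_major = rep(alleles[1], nm),
      allele_minor = rep(alleles[2], nm),
      stringsAsFactors = FALSE
    ),
    entries = if (is.null(colnames(calls)))
      sprintf("E%02d", seq_len(ncol(calls))) else colnames(calls),
    depth = depth
  )
}

# Oracle: allele counts enumerated call-by-call (HOM = 2 copies, HET = 1+1).
oracle_marker_stats <- function(gm) {
  t(vapply(seq_len(nrow(gm$calls)), function(i) {
    major <- 0; minor <- 0; het <- 0; miss <- 0
    for (code in gm$calls[i, ]) {
      if (is.na(code)) { miss <- miss + 1 }
      else if (code == 0) { major <- major + 2 }
      else if (code == 1) { major <- major + 1; minor <- minor + 1; het <- het + 1 }
      else { minor <- minor + 2 }
    }
    total <- major + minor
    q <- if (total == 0) NA_real_ else minor / total
    p <- 1 - q
    non_missing <- length(gm$calls[i, ]) - miss
    c(maf = min(q, 1 - q),
      het_rate = if (non_missing == 0) NA_real_ else het / non_missing,
      missing_rate = miss / length(gm$calls[i, ]),
      pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2)
  }, c(maf = 0, het_rate = 0, missing_rate = 0, pic = 0)))
}

# Oracle: exhaustive pairwise mismatch counting for panel evaluation.
oracle_evaluate <- function(gm, marker_ids) {
  sub <- if (length(marker_ids) == 0) NULL
         else gm$calls[match(marker_ids, gm$markers$marker_id), , drop = FALSE]
  n <- length(gm$entries)
  counts <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cnt <- 0L
      if (!is.null(sub)) {
        for (m in seq_len(nrow(sub))) {
          a <- sub[m, i]; b <- sub[m, j]
          if (!is.na(a) && !is.na(b) && a != b) cnt <- cnt + 1L
        }
      }
      counts <- c(counts, cnt)
    }
  }
  list(proportion = mean(counts == 0), counts = counts,
       min = min(counts), mean = mean(counts))
}

# Oracle: exhaustive subset search, ranked by the same lexicographic keys
# (ascending proportion, descending min mismatch, descending mean).
oracle_best_subset <- function(gm, candidates, size) {
  combos <- utils::combn(candidates, size, simplify = FALSE)
  evs <- lapply(combos, function(ids) oracle_evaluate(gm, ids))
  prop <- vapply(evs, `[[`, numeric(1), "proportion")
  minm <- vapply(evs, `[[`, numeric(1), "min")
  meanm <- vapply(evs, `[[`, numeric(1), "mean")
  i <- order(prop, -minm, -meanm)[1]
  list(ids = combos[[i]], proportion = prop[i], min = minm[i],
       mean = meanm[i])
}

# 12 lines whose identity is carried entirely by five "ID" markers (codes 0
# or 2 encode a 5-bit word, including all Hamming-1 neighbours of 00000),
# padded with monomorphic markers. The five ID markers are the unique
# 5-marker subset distinguishing every pair.
make_planted_id_panel <- function(n_pad = 3) {
  words <- rbind(
    c(0, 0, 0, 0, 0),
    diag(5),
    c(1, 1, 0, 0, 0), c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0),
    c(0, 0, 0, 1, 1), c(1, 0, 1, 0, 1), c(1, 1, 1, 1, 1)
  )
  calls <- rbind(t(words) * 2L, matrix(0L, n_pad, nrow(words)))
  gm <- make_gm(calls)
  list(gm = gm, id_markers = gm$markers$marker_id[1:5],
       pad_markers = gm$markers$marker_id[-(1:5)])
}
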