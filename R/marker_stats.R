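# Per-marker informativeness statistics and pairwise linkage disequilibrium.

#' Compute per-marker informativeness statistics
#'
#' For each marker, counts alleles over non-missing calls (a homozygote
#' contributes two copies of its allele, a heterozygote one of each) and
#' derives:
#' \describe{
#'   \item{maf}{minor allele frequency, `min(p, q)` of the two allele
#'     frequencies, in \[0, 0.5\].}
#'   \item{het_rate}{heterogeneity: fraction of HET calls among non-missing
#'     calls.}
#'   \item{missing_rate}{fraction of missing calls among all entries.}
#'   \item{pic}{polymorphic information content in its biallelic closed
#'     form, `1 - (p^2 + q^2) - 2 p^2 q^2` (Botstein et al.), maximal at
#'     0.375 when p = q = 0.5.}
#'   \item{coverage}{mean reads per allele, `NA` when the matrix carries no
#'     depth.}
#'   \item{mutation_class}{`AG_TC` for A/G or T/C substitutions (transitions),
#'     `AC_TG` for A/C or G/T, `AT_CG` for A/T or C/G.}
#' }
#' Note that `het_rate` and `missing_rate` use different denominators
#' (non-missing calls vs all entries), so they need not sum below 1.
#' Markers with every call missing get `NA` for maf, het_rate and pic and
#' are flagged in the `all_missing` column.
#'
#' @param gm A [genotype_matrix()].
#' @return A data frame with one row per marker: `marker_id`, `chrom`,
#'   `pos`, `maf`, `het_rate`, `missing_rate`, `pic`, `coverage`,
#'   `mutation_class`, `all_missing`.
#' @export
compute_marker_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  n_entries <- ncol(calls)
  non_missing <- rowSums(!is.na(calls))
  minor_alleles <- rowSums(calls, na.rm = TRUE)
  total_alleles <- 2 * non_missing
  q <- ifelse(total_alleles > 0, minor_alleles / total_alleles, NA_real_)
  maf <- pmin(q, 1 - q)
  het_rate <- ifelse(non_missing > 0,
                     rowSums(calls == CALL_HET, na.rm = TRUE) / non_missing,
                     NA_real_)
  missing_rate <- rowSums(is.na(calls)) / n_entries
  p <- 1 - q
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  data.frame(
    marker_id = gm$markers$marker_id,
    chrom = gm$markers$chrom,
    pos = gm$markers$pos,
    maf = maf,
    het_rate = het_rate,
    missing_rate = missing_rate,
    pic = pic,
    coverage = if (is.null(gm$depth)) NA_real_ else gm$depth,
    mutation_class = mutation_class(gm$markers$allele_major,
                                    gm$markers$allele_minor),
    all_missing = non_missing == 0,
    stringsAsFactors = FALSE
  )
}

#' Classify a SNP substitution by its allele pair
#'
#' @param a1,a2 Character vectors of single bases.
#' @return `"AG_TC"` (transitions), `"AC_TG"`, or `"AT_CG"`.
#' @export
mutation_class <- function(a1, a2) {
  pair <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out <- rep(NA_character_, length(pair))
  out[pair %in% c("A/G", "C/T")] <- "AG_TC"
  out[pair %in% c("A/C", "G/T")] <- "AC_TG"
  out[pair %in% c("A/T", "C/G")] <- "AT_CG"
  if (anyNA(out)) stop("invalid allele pair(s): ",
                       paste(unique(pair[is.na(out)]), collapse = ", "))
  out
}

#' Summarise the mutation-class composition of a marker set
#'
#' @param stats Marker statistics from [compute_marker_stats()], or any data
#'   frame with a `mutation_class` column.
#' @return Named numeric vector of fractions over `AG_TC`, `AC_TG`,
#'   `AT_CG`, summing to 1.
#' @export
mutation_class_summary <- function(stats) {
  cls <- factor(stats$mutation_class, levels = c("AG_TC", "AC_TG", "AT_CG"))
  if (length(cls) == 0) stop("empty marker list")
  tab <- table(cls)
  frac <- as.numeric(tab) / length(cls)
  names(frac) <- names(tab)
  frac
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Uses only entries homozygous at both loci, each contributing one
#' two-locus haplotype, and returns the squared correlation
#' `r2 = D^2 / (pA qA pB qB)` with `D = p(AB) - pA pB`. Heterozygous calls
#' are dropped rather than phased: in a near-fully homozygous inbred panel
#' they carry almost no haplotype information.
#'
#' @param gm A `genotype_matrix`.
#' @param marker_a,marker_b Marker ids.
#' @return r-squared in \[0, 1\], or `NA` with a warning when fewer than two
#'   doubly homozygous entries remain or either locus is monomorphic among
#'   them.
#' @export
ld_r2 <- function(gm, marker_a, marker_b) {
  ia <- match(marker_a, gm$markers$marker_id)
  ib <- match(marker_b, gm$markers$marker_id)
  if (is.na(ia) || is.na(ib)) stop("unknown marker id")
  a <- gm$calls[ia, ]
  b <- gm$calls[ib, ]
  use <- !is.na(a) & !is.na(b) & a != CALL_HET & b != CALL_HET
  if (sum(use) < 2) {
    warning("fewer than 2 entries homozygous at both loci")
    return(NA_real_)
  }
  ha <- a[use] / 2  # 0 = major, 1 = minor haplotype allele
  hb <- b[use] / 2
  pA <- mean(ha)
  pB <- mean(hb)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warning("locus monomorphic among doubly homozygous entries")
    return(NA_real_)
  }
  D <- mean(ha * hb) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Write a marker statistics table as TSV
#'
#' @param stats Data frame from [compute_marker_stats()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_marker_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
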