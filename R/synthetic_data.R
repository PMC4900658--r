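# Seeded simulator of structured inbred-line panels, regeneration series and
# QC failure modes (contamination, mislabeling). Provides the ground truth
# against which the statistics, panel search and blind-test modules are
# validated.

# Maize-like karyotype: ten chromosomes, approximate physical lengths in bp.
MAIZE_CHROM_BP <- c(`1` = 301e6, `2` = 238e6, `3` = 232e6, `4` = 242e6,
                    `5` = 217e6, `6` = 169e6, `7` = 177e6, `8` = 175e6,
                    `9` = 157e6, `10` = 149e6)

#' Configuration for the inbred-panel simulator
#'
#' Defaults emulate the marker profile of a filtered DArTseq maize inbred
#' panel: residual heterogeneity near 5%, missing data near 18%, minor
#' allele frequencies averaging roughly 0.16 (drawn from a right-skewed
#' Beta), transition (A/G, T/C) substitutions at about 61%, and mean read
#' depth near 8 with enough spread that a \[2, 15\] coverage filter removes
#' markers at both tails.
#'
#' @param n_lines Number of inbred lines.
#' @param n_markers Number of SNP markers.
#' @param n_groups Number of population groups (heterotic pools).
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param divergence Half-width of the uniform spread of group allele
#'   frequencies around the global frequency, in \[0, 0.5\].
#' @param residual_het Per-call probability of residual heterozygosity.
#' @param missing_rate Per-call missing probability.
#' @param depth_mean,depth_dispersion Gamma model of per-marker mean reads
#'   per allele: shape `1/dispersion`, scale `mean * dispersion`.
#' @param mutation_probs Probabilities of the three substitution classes
#'   (`AG_TC`, `AC_TG`, `AT_CG`), summing to 1.
#' @param seed Integer seed (mandatory; every draw is reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = 48, n_markers = 1000, n_groups = 3,
                       chromosomes = MAIZE_CHROM_BP, divergence = 0.2,
                       residual_het = 0.05, missing_rate = 0.18,
                       depth_mean = 8, depth_dispersion = 0.5,
                       mutation_probs = c(AG_TC = 0.607, AC_TG = 0.195,
                                          AT_CG = 0.198),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- c(divergence, residual_het, missing_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(sum(mutation_probs) - 1) > 1e-12)
    stop("mutation_probs must sum to 1")
  if (n_groups > n_lines) stop("more groups than lines")
  structure(list(n_lines = n_lines, n_markers = n_markers,
                 n_groups = n_groups, chromosomes = chromosomes,
                 divergence = divergence, residual_het = residual_het,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 mutation_probs = mutation_probs, seed = as.integer(seed)),
            class = "sim_config")
}

ALLELE_PAIRS <- list(AG_TC = list(c("A", "G"), c("T", "C")),
                     AC_TG = list(c("A", "C"), c("T", "G")),
                     AT_CG = list(c("A", "T"), c("C", "G")))

#' Simulate a structured reference panel of inbred lines
#'
#' Draws, per marker, a global minor-allele frequency from a right-skewed
#' Beta(1.3, 5.5) clipped to \[0.02, 0.5\], then group frequencies
#' uniformly within `divergence` of it (truncated to \[0, 1\]). Each line
#' is homozygous minor with its group's frequency, after which residual
#' heterozygosity and missingness are overlaid call-by-call. Marker
#' positions are uniform within chromosomes sampled proportionally to
#' length; per-marker depth follows the configured Gamma.
#'
#' @param config A [sim_config()].
#' @return A list: `gm` (a [genotype_matrix()] with depth) and `truth`
#'   (list with `group`: named group id per line, `group_freq`: markers x
#'   groups frequency matrix, `config`).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_markers
  nl <- config$n_lines
  chroms <- names(config$chromosomes)
  chrom <- sample(chroms, nm, replace = TRUE,
                  prob = config$chromosomes / sum(config$chromosomes))
  pos <- vapply(chrom, function(ch)
    sample.int(config$chromosomes[[ch]], 1), integer(1))
  cls <- sample(names(config$mutation_probs), nm, replace = TRUE,
                prob = config$mutation_probs)
  alleles <- t(vapply(cls, function(cl) {
    pair <- ALLELE_PAIRS[[cl]][[sample.int(2, 1)]]
    sample(pair)
  }, character(2)))
  markers <- data.frame(
    marker_id = sprintf("M%05d", seq_len(nm)),
    chrom = chrom, pos = as.integer(pos),
    allele_major = alleles[, 1], allele_minor = alleles[, 2],
    stringsAsFactors = FALSE
  )
  q0 <- pmin(pmax(stats::rbeta(nm, 1.3, 5.5), 0.02), 0.5)
  gfreq <- matrix(0, nm, config$n_groups)
  for (g in seq_len(config$n_groups)) {
    gfreq[, g] <- pmin(pmax(q0 + stats::runif(nm, -config$divergence,
                                              config$divergence), 0), 1)
  }
  group <- rep(seq_len(config$n_groups), length.out = nl)
  lines <- sprintf("L%03d", seq_len(nl))
  names(group) <- lines
  calls <- matrix(0L, nm, nl)
  for (j in seq_len(nl)) {
    calls[, j] <- 2L * (stats::runif(nm) < gfreq[, group[j]])
  }
  if (config$residual_het > 0) {
    het <- matrix(stats::runif(nm * nl) < config$residual_het, nm, nl)
    calls[het] <- 1L
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(nm * nl) < config$missing_rate, nm, nl)
    calls[miss] <- NA_integer_
  }
  depth <- stats::rgamma(nm, shape = 1 / config$depth_dispersion,
                         scale = config$depth_mean * config$depth_dispersion)
  gm <- genotype_matrix(calls, markers, lines, depth = depth)
  list(gm = gm, truth = list(group = group, group_freq = gfreq,
                             config = config))
}

#' Simulate a regeneration series of one line
#'
#' Each generation copies its parent profile, changing each non-missing
#' call independently with probability `drift_rate` (a homozygote becomes
#' the opposite homozygote; a heterozygote fixes to a random homozygote).
#' With `purify = TRUE`, each residual heterozygous call is additionally
#' fixed with probability 0.5 per generation — halving the expected
#' heterogeneity each cycle, as a phenotypic purification procedure does.
#'
#' @param gm A [genotype_matrix()] holding the source line.
#' @param line Entry label of the source line.
#' @param n_gens Number of regeneration cycles.
#' @param drift_rate Per-marker change probability per cycle, in \[0, 1\].
#' @param purify Apply the HET-halving purification model.
#' @param seed Integer seed.
#' @return A list: `profiles` (named list `gen1`..`genN` of call-code
#'   vectors named by marker id) and `lineage` (data frame generation,
#'   parent).
#' @export
simulate_regenerations <- function(gm, line, n_gens = 1, drift_rate = 0,
                                   purify = FALSE, seed = 1) {
  stopifnot(drift_rate >= 0, drift_rate <= 1)
  idx <- match(line, gm$entries)
  if (is.na(idx)) stop("unknown line: ", line)
  set.seed(seed)
  parent <- gm$calls[, idx]
  names(parent) <- gm$markers$marker_id
  profiles <- vector("list", n_gens)
  lineage <- data.frame(generation = character(0), parent = character(0))
  parent_name <- line
  for (g in seq_len(n_gens)) {
    prof <- parent
    ok <- !is.na(prof)
    if (purify) {
      fix <- ok & prof == CALL_HET & stats::runif(length(prof)) < 0.5
      prof[fix] <- 2L * (stats::runif(length(prof)) < 0.5)[fix]
    }
    if (drift_rate > 0) {
      change <- ok & stats::runif(length(prof)) < drift_rate
      hom <- change & prof != CALL_HET
      prof[hom] <- 2L - prof[hom]
      hetc <- change & prof == CALL_HET
      prof[hetc] <- 2L * (stats::runif(length(prof)) < 0.5)[hetc]
    }
    gen_name <- paste0(line, "_gen", g)
    profiles[[g]] <- prof
    names(profiles)[g] <- gen_name
    lineage <- rbind(lineage, data.frame(generation = gen_name,
                                         parent = parent_name))
    parent <- prof
    parent_name <- gen_name
  }
  list(profiles = profiles, lineage = lineage)
}

#' Replicate an entry's reference profile into individual plants
#'
#' @param gm A `genotype_matrix`.
#' @param line Entry label.
#' @param n Number of individuals.
#' @return Markers x individuals matrix of call codes (columns
#'   `<line>_i001`, ...).
#' @export
entry_individuals <- function(gm, line, n) {
  idx <- match(line, gm$entries)
  if (is.na(idx)) stop("unknown line: ", line)
  mat <- matrix(gm$calls[, idx], nrow = nrow(gm$calls), ncol = n)
  dimnames(mat) <- list(gm$markers$marker_id,
                        sprintf("%s_i%03d", line, seq_len(n)))
  mat
}

#' Inject contamination and label swaps into an entry's individuals
#'
#' Each individual is independently replaced by the contaminant's profile
#' with probability `rate`; listed column-label swaps are then applied.
#' Every planted event is recorded in the returned truth.
#'
#' @param individuals Markers x individuals matrix of call codes.
#' @param contaminant Named call-code vector (or one-entry
#'   `genotype_matrix`) covering the individuals' markers.
#' @param rate Per-individual contamination probability in \[0, 1\].
#' @param label_swaps Optional list of length-2 character vectors of
#'   individual labels to swap.
#' @param seed Integer seed.
#' @return A list: `individuals` (modified matrix) and `truth` (list with
#'   `contaminated` labels and `swapped` pairs).
#' @export
inject_off_types <- function(individuals, contaminant, rate = 0,
                             label_swaps = NULL, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  mat <- as.matrix(individuals)
  prof <- as_profile(contaminant)
  if (!all(rownames(mat) %in% names(prof)))
    stop("contaminant profile lacks markers of the individuals")
  prof <- prof[rownames(mat)]
  same <- apply(mat, 2, function(col) {
    ok <- !is.na(col) & !is.na(prof)
    all(col[ok] == prof[ok])
  })
  if (all(same))
    warning("contaminant is indistinguishable from the entry profile")
  set.seed(seed)
  hit <- stats::runif(ncol(mat)) < rate
  mat[, hit] <- prof
  contaminated <- colnames(mat)[hit]
  if (!is.null(label_swaps)) {
    for (sw in label_swaps) {
      i <- match(sw[1], colnames(mat))
      j <- match(sw[2], colnames(mat))
      if (is.na(i) || is.na(j)) stop("swap label not found: ",
                                     paste(sw, collapse = ", "))
      colnames(mat)[c(i, j)] <- colnames(mat)[c(j, i)]
    }
  }
  list(individuals = mat,
       truth = list(contaminated = contaminated,
                    swapped = label_swaps %||% list()))
}
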