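# Readers and writers for the three interchange formats: a DArT-style TSV
# matrix, VCF 4.x (GT field only), and HapMap diploid text. Per-marker mean
# read depth travels in a two-column sidecar TSV for every format.

MISSING_CODES <- c("--", "NN", "N", "", "??")

#' Read a genotype matrix from file
#'
#' Parses diploid biallelic SNP records into a [genotype_matrix()]. Records
#' that are multi-allelic, non-SNP, or malformed are skipped and reported in
#' the `"skipped"` attribute of the result. Heterozygous calls in any phase
#' map to the single unphased HET state. Major/minor alleles are assigned by
#' observed frequency (ties broken alphabetically), so downstream statistics
#' are independent of the file's allele orientation.
#'
#' @param path Path to the input file.
#' @param format One of `"tsv"`, `"vcf"`, `"hapmap"`.
#' @param depth_path Optional path to a two-column TSV (`marker_id`,
#'   `depth`) of mean reads per allele. When `NULL`, a sidecar file named
#'   `<path>.depth.tsv` is loaded if present.
#' @return A `genotype_matrix` with attribute `"skipped"`: a data frame of
#'   skipped records and the reason each was rejected.
#' @seealso [write_genotype_matrix()]
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf", "hapmap"),
                                 depth_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  parsed <- switch(format,
    tsv = parse_tsv_matrix(path),
    vcf = parse_vcf_matrix(path),
    hapmap = parse_hapmap_matrix(path)
  )
  if (nrow(parsed$markers) == 0)
    stop("no valid biallelic SNP records in ", path)
  gm <- genotype_matrix(parsed$calls, parsed$markers, parsed$entries)
  gm <- canonicalize_alleles(gm)
  if (is.null(depth_path)) {
    sidecar <- paste0(path, ".depth.tsv")
    if (file.exists(sidecar)) depth_path <- sidecar
  }
  if (!is.null(depth_path)) gm$depth <- read_depth_table(depth_path, gm)
  attr(gm, "skipped") <- parsed$skipped
  gm
}

#' Write a genotype matrix to file
#'
#' Emits a file that [read_genotype_matrix()] parses back losslessly (calls,
#' marker order, metadata). When depth is present it is written to a sidecar
#' TSV `<path>.depth.tsv`, since none of the formats carries per-marker mean
#' depth natively.
#'
#' @param gm A `genotype_matrix`.
#' @inheritParams read_genotype_matrix
#' @return The path written, invisibly.
#' @export
write_genotype_matrix <- function(gm, path, format = c("tsv", "vcf", "hapmap")) {
  format <- match.arg(format)
  validate_genotype_matrix(gm)
  lines <- switch(format,
    tsv = format_tsv_matrix(gm),
    vcf = format_vcf_matrix(gm),
    hapmap = format_hapmap_matrix(gm)
  )
  writeLines(lines, path)
  if (!is.null(gm$depth)) {
    depth_df <- data.frame(marker_id = gm$markers$marker_id,
                           depth = sprintf("%.17g", gm$depth))
    utils::write.table(depth_df, paste0(path, ".depth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Orient every marker so the major allele is the more frequent one
#'
#' Recounts alleles from the calls and swaps major/minor (flipping call
#' codes 0 and 2) wherever the stored minor allele is in fact the commoner,
#' with frequency ties broken alphabetically. Applied automatically by
#' [read_genotype_matrix()].
#'
#' @param gm A `genotype_matrix`.
#' @return The reoriented `genotype_matrix`.
#' @export
canonicalize_alleles <- function(gm) {
  for (i in seq_len(nrow(gm$calls))) {
    row <- gm$calls[i, ]
    minor_count <- sum(row, na.rm = TRUE)          # minor alleles observed
    total <- 2L * sum(!is.na(row))
    major_count <- total - minor_count
    swap <- if (minor_count != major_count) minor_count > major_count
            else gm$markers$allele_minor[i] < gm$markers$allele_major[i]
    if (swap) {
      gm$calls[i, ] <- 2L - row
      tmp <- gm$markers$allele_major[i]
      gm$markers$allele_major[i] <- gm$markers$allele_minor[i]
      gm$markers$allele_minor[i] <- tmp
    }
  }
  gm
}

read_depth_table <- function(path, gm) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  idx <- match(gm$markers$marker_id, df[[1]])
  if (anyNA(idx))
    stop("depth table lacks marker(s): ",
         paste(gm$markers$marker_id[is.na(idx)][1:5], collapse = ", "))
  as.numeric(df[[2]][idx])
}

# --- two-letter genotype strings (TSV and HapMap body) -----------------------

decode_diploid_strings <- function(geno, a1, a2) {
  out <- rep(NA_integer_, length(geno))
  geno <- toupper(geno)
  miss <- geno %in% MISSING_CODES
  hom1 <- geno == paste0(a1, a1)
  hom2 <- geno == paste0(a2, a2)
  het <- geno %in% c(paste0(a1, a2), paste0(a2, a1))
  bad <- !(miss | hom1 | hom2 | het)
  if (any(bad)) return(NULL)  # caller skips the record
  out[hom1] <- 0L
  out[het] <- 1L
  out[hom2] <- 2L
  out
}

encode_diploid_strings <- function(codes, a1, a2, missing_code = "--") {
  out <- rep(missing_code, length(codes))
  out[!is.na(codes) & codes == 0L] <- paste0(a1, a1)
  out[!is.na(codes) & codes == 1L] <- paste0(a1, a2)
  out[!is.na(codes) & codes == 2L] <- paste0(a2, a2)
  out
}

parse_allele_pair <- function(s) {
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  if (!all(parts %in% VALID_BASES) || parts[1] == parts[2]) return(NULL)
  parts
}

# --- TSV dialect -------------------------------------------------------------
# marker_id  chrom  pos  alleles  <entry1>  <entry2> ...
# alleles as "A/G"; calls as two-letter strings; "--" or "NN" missing.

parse_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 5)
    stop("TSV matrix needs marker_id, chrom, pos, alleles plus >= 1 entry")
  entries <- names(df)[-(1:4)]
  n <- nrow(df)
  keep <- logical(n)
  skipped <- list()
  calls <- matrix(NA_integer_, n, length(entries))
  markers <- data.frame(marker_id = df[[1]], chrom = df[[2]],
                        pos = suppressWarnings(as.integer(df[[3]])),
                        allele_major = NA_character_,
                        allele_minor = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    al <- parse_allele_pair(df[[4]][i])
    if (is.null(al)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = df[[1]][i],
                   reason = "not a biallelic SNP allele pair")
      next
    }
    codes <- decode_diploid_strings(unlist(df[i, -(1:4)], use.names = FALSE),
                                    al[1], al[2])
    if (is.null(codes)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = df[[1]][i],
                   reason = "call inconsistent with declared alleles")
      next
    }
    markers$allele_major[i] <- al[1]
    markers$allele_minor[i] <- al[2]
    calls[i, ] <- codes
    keep[i] <- TRUE
  }
  list(calls = calls[keep, , drop = FALSE],
       markers = markers[keep, , drop = FALSE],
       entries = entries,
       skipped = bind_skip_rows(skipped))
}

format_tsv_matrix <- function(gm) {
  m <- gm$markers
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(m$marker_id[i], m$chrom[i], m$pos[i],
            paste0(m$allele_major[i], "/", m$allele_minor[i]),
            encode_diploid_strings(gm$calls[i, ], m$allele_major[i],
                                   m$allele_minor[i])),
          collapse = "\t")
  }, character(1))
  c(paste(c("marker_id", "chrom", "pos", "alleles", gm$entries),
          collapse = "\t"), body)
}

# --- VCF ---------------------------------------------------------------------

parse_vcf_matrix <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  entries <- colnames(gt)
  n <- nrow(fix)
  keep <- logical(n)
  skipped <- list()
  calls <- matrix(NA_integer_, n, length(entries))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  markers <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        allele_major = fix[, "REF"],
                        allele_minor = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ref <- markers$allele_major[i]; alt <- markers$allele_minor[i]
    if (is.na(alt) || grepl(",", alt, fixed = TRUE)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = ids[i], reason = "multi-allelic site")
      next
    }
    if (!ref %in% VALID_BASES || !alt %in% VALID_BASES) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = ids[i], reason = "not a SNP")
      next
    }
    codes <- decode_vcf_gt(gt[i, ])
    if (is.null(codes)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = ids[i], reason = "unparseable GT")
      next
    }
    calls[i, ] <- codes
    keep[i] <- TRUE
  }
  list(calls = calls[keep, , drop = FALSE],
       markers = markers[keep, , drop = FALSE],
       entries = entries,
       skipped = bind_skip_rows(skipped))
}

decode_vcf_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  miss <- is.na(gt) | gt %in% c("./.", ".", "./", "/.")
  hom0 <- gt == "0/0"
  het <- gt %in% c("0/1", "1/0")
  hom1 <- gt == "1/1"
  if (any(!(miss | hom0 | het | hom1))) return(NULL)
  out[hom0] <- 0L
  out[het] <- 1L
  out[hom1] <- 2L
  out
}

format_vcf_matrix <- function(gm) {
  m <- gm$markers
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(m)), function(i) {
    gts <- ifelse(is.na(gm$calls[i, ]), "./.", gt_codes[gm$calls[i, ] + 1L])
    paste(c(m$chrom[i], m$pos[i], m$marker_id[i], m$allele_major[i],
            m$allele_minor[i], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  c("##fileformat=VCFv4.2",
    "##source=panelqc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$entries), collapse = "\t"),
    body)
}

# --- HapMap diploid text -----------------------------------------------------

HAPMAP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

parse_hapmap_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", colClasses = "character")
  if (ncol(df) < 12)
    stop("HapMap file needs 11 metadata columns plus >= 1 entry")
  entries <- names(df)[-(1:11)]
  n <- nrow(df)
  keep <- logical(n)
  skipped <- list()
  calls <- matrix(NA_integer_, n, length(entries))
  markers <- data.frame(marker_id = df[[1]], chrom = df[[3]],
                        pos = suppressWarnings(as.integer(df[[4]])),
                        allele_major = NA_character_,
                        allele_minor = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    al <- parse_allele_pair(df[[2]][i])
    if (is.null(al)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = df[[1]][i],
                   reason = "not a biallelic SNP allele pair")
      next
    }
    codes <- decode_diploid_strings(unlist(df[i, -(1:11)], use.names = FALSE),
                                    al[1], al[2])
    if (is.null(codes)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = i, marker_id = df[[1]][i],
                   reason = "call inconsistent with declared alleles")
      next
    }
    markers$allele_major[i] <- al[1]
    markers$allele_minor[i] <- al[2]
    calls[i, ] <- codes
    keep[i] <- TRUE
  }
  list(calls = calls[keep, , drop = FALSE],
       markers = markers[keep, , drop = FALSE],
       entries = entries,
       skipped = bind_skip_rows(skipped))
}

format_hapmap_matrix <- function(gm) {
  m <- gm$markers
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(m$marker_id[i], paste0(m$allele_major[i], "/", m$allele_minor[i]),
            m$chrom[i], m$pos[i], "+", "NA", "NA", "NA", "NA", "NA", "NA",
            encode_diploid_strings(gm$calls[i, ], m$allele_major[i],
                                   m$allele_minor[i], missing_code = "NN")),
          collapse = "\t")
  }, character(1))
  c(paste(c(HAPMAP_META, gm$entries), collapse = "\t"), body)
}

bind_skip_rows <- function(rows) {
  if (length(rows) == 0)
    return(data.frame(row = integer(0), marker_id = character(0),
                      reason = character(0)))
  do.call(rbind, rows)
}
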