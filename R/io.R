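## Data containers and file formats.
##
## Conventions used throughout the package:
##   * coordinates are 1-based inclusive bp positions (VCF convention);
##   * the bp length of a segment is end_bp - start_bp;
##   * genotype dosages count copies of the alt allele (0/1/2, NA = missing);
##   * haplotype alleles are 0 (ref), 1 (alt) or NA;
##   * allele orientation is ref/alt, never ancestral/derived -- the focal
##     risk allele is always named explicitly by the user.

#' Construct a genotype matrix
#'
#' The genotype container used by every genotype-level analysis: a samples x
#' variants matrix of alt-allele dosages together with the variant map.
#' Variants are sorted by chromosome and position on construction; only
#' biallelic sites with strictly increasing positions within a chromosome are
#' accepted.
#'
#' @param calls Integer matrix of alt-allele dosages in \{0, 1, 2\}, `NA` for
#'   missing; samples in rows, variants in columns.
#' @param samples Character vector of unique sample IDs (one per row).
#' @param variants `data.frame` with columns `chrom`, `pos_bp`, `id`, `ref`,
#'   `alt` (one row per column of `calls`).
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `samples`, `variants`.
#' @export
genotype_matrix <- function(calls, samples, variants) {
  calls <- as.matrix(calls)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample IDs")
  need <- c("chrom", "pos_bp", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    stop("calls dimensions do not match samples/variants")
  }
  variants <- variants[, need]
  variants$chrom <- as.character(variants$chrom)
  ord <- order(variants$chrom, variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(variants) <- NULL
  for (ch in unique(variants$chrom)) {
    p <- variants$pos_bp[variants$chrom == ch]
    if (anyDuplicated(p)) stop("duplicated bp position on chromosome ", ch)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, variants$id)
  structure(list(calls = calls, samples = samples, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d chromosomes)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Number of samples / variants
#' @param x A `genotype_matrix` or `haplotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Construct a phased haplotype matrix
#'
#' Holds the output of phasing: two haplotype rows per sample, in
#' sample-major order (sample 1 phase 0, sample 1 phase 1, sample 2 phase 0,
#' ...). Collapsing the two phases of each sample reproduces the genotype
#' dosages (see [as_genotype_matrix()]).
#'
#' @param alleles Integer matrix of alleles in \{0, 1\} (`NA` = missing),
#'   one haplotype per row, variants in columns.
#' @param samples Character vector of sample IDs (length `nrow(alleles) / 2`).
#' @param variants Variant `data.frame` as in [genotype_matrix()].
#' @return An object of class `haplotype_matrix` with elements `alleles`,
#'   `samples`, `sample_of_hap`, `phase_of_hap`, `variants`. Haplotype row
#'   names are `"<sample>_<phase>"`.
#' @export
haplotype_matrix <- function(alleles, samples, variants) {
  alleles <- as.matrix(alleles)
  samples <- as.character(samples)
  if (nrow(alleles) != 2L * length(samples)) {
    stop("alleles must have exactly two rows per sample")
  }
  if (anyDuplicated(samples)) stop("duplicated sample IDs")
  need <- c("chrom", "pos_bp", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns: ", paste(need, collapse = ", "))
  }
  if (ncol(alleles) != nrow(variants)) {
    stop("alleles dimensions do not match variants")
  }
  variants <- variants[, need]
  variants$chrom <- as.character(variants$chrom)
  ord <- order(variants$chrom, variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  alleles <- alleles[, ord, drop = FALSE]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos_bp[variants$chrom == ch]
    if (anyDuplicated(p)) stop("duplicated bp position on chromosome ", ch)
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0, 1 or NA")
  }
  sample_of_hap <- rep(samples, each = 2L)
  phase_of_hap <- rep(c(0L, 1L), times = length(samples))
  dimnames(alleles) <- list(paste0(sample_of_hap, "_", phase_of_hap),
                            variants$id)
  structure(list(alleles = alleles, samples = samples,
                 sample_of_hap = sample_of_hap, phase_of_hap = phase_of_hap,
                 variants = variants),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$alleles), length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Haplotype row IDs
#' @param hm A `haplotype_matrix`.
#' @return Character vector `"<sample>_<phase>"`, one per haplotype row.
#' @export
hap_ids <- function(hm) rownames(hm$alleles)

#' Collapse phased haplotypes to genotype dosages
#'
#' @param hm A `haplotype_matrix`.
#' @return A `genotype_matrix`; a dosage is `NA` where either phase is
#'   missing.
#' @export
as_genotype_matrix <- function(hm) {
  i0 <- seq(1L, nrow(hm$alleles), by = 2L)
  calls <- hm$alleles[i0, , drop = FALSE] + hm$alleles[i0 + 1L, , drop = FALSE]
  genotype_matrix(calls, hm$samples, hm$variants)
}

## ---------------------------------------------------------------------------
## Phased VCF

.is_autosome <- function(chrom) {
  core <- sub("^[Cc]hr", "", chrom)
  !core %in% c("X", "Y", "MT", "M", "XY")
}

#' Read a phased VCF into a haplotype matrix
#'
#' Retains biallelic autosomal SNVs only; multi-allelic records, indels and
#' sex-chromosome/mitochondrial sites are skipped and counted. Heterozygous
#' unphased calls (`"0/1"`) are an error unless `permissive = TRUE`, in which
#' case they are set to missing (homozygous unphased calls are phase-
#' unambiguous and accepted as is).
#'
#' @param path Path to a VCF (4.x) file with GT fields.
#' @param permissive Treat heterozygous unphased calls as missing instead of
#'   erroring.
#' @return A list with `hap` (`haplotype_matrix`), `gen` (`genotype_matrix`
#'   collapsed from it), and `n_skipped` (records dropped by the biallelic
#'   autosomal SNV filter).
#' @export
read_phased_vcf <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt & .is_autosome(fix$CHROM)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " non-SNV/multi-allelic/non-autosomal record(s) skipped")
  }
  if (!any(keep)) stop("no biallelic autosomal SNVs in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  a0 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a1 <- substr(gt, 3L, 3L)
  a0[a0 == "." | a0 == ""] <- NA
  a1[a1 == "." | a1 == ""] <- NA
  het_unphased <- !is.na(a0) & !is.na(a1) & sep == "/" & a0 != a1
  if (any(het_unphased)) {
    if (!permissive) {
      stop("heterozygous unphased GT call(s) present (e.g. variant ",
           fix$ID[which(rowSums(het_unphased) > 0)[1]],
           "); rerun with permissive = TRUE to treat them as missing")
    }
    a0[het_unphased] <- NA
    a1[het_unphased] <- NA
  }
  M <- nrow(fix)
  N <- length(samples)
  alleles <- matrix(NA_integer_, 2L * N, M)
  for (s in seq_len(N)) {
    alleles[2L * s - 1L, ] <- suppressWarnings(as.integer(a0[, s]))
    alleles[2L * s, ]      <- suppressWarnings(as.integer(a1[, s]))
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("malformed VCF: allele index other than 0/1 at a retained site")
  }
  variants <- data.frame(chrom = fix$CHROM,
                         pos_bp = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  hm <- haplotype_matrix(alleles, samples, variants)
  list(hap = hm, gen = as_genotype_matrix(hm), n_skipped = n_skipped)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Minimal VCF 4.2 writer with phased GT fields (`a|b`); missing alleles are
#' written as `.`. Round-trips through [read_phased_vcf()].
#'
#' @param hm A `haplotype_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hm, path) {
  v <- hm$variants
  N <- length(hm$samples)
  al <- hm$alleles
  ach <- matrix(as.character(al), nrow(al), ncol(al))
  ach[is.na(ach)] <- "."
  gt_cols <- vapply(seq_len(N), function(s) {
    paste0(ach[2L * s - 1L, ], "|", ach[2L * s, ])
  }, character(nrow(v)))
  if (nrow(v) == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  header <- c("##fileformat=VCFv4.2",
              "##source=founderhap",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", hm$samples), collapse = "\t"))
  body <- cbind(v$chrom, v$pos_bp, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                gt_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## PLINK text PED/MAP

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Allele coding is normalised per site against the first-seen non-missing
#' allele (taken as ref, dosage counts the other allele); `0 0` encodes a
#' missing genotype. The chosen ref/alt alleles are recorded in the variant
#' table.
#'
#' @param ped_path Path to the whitespace-delimited PED file
#'   (FID IID PAT MAT SEX PHENO + two allele columns per variant).
#' @param map_path Path to the MAP file (chrom, id, cM, bp).
#' @return A `genotype_matrix`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos_bp")
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  M <- nrow(map)
  if (ncol(ped) != 6L + 2L * M) {
    bad <- ped[[2]][1]
    stop("PED row length (", ncol(ped), " fields) does not match MAP (",
         M, " variants); first sample: ", bad)
  }
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(M) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(M), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  calls <- matrix(NA_integer_, nrow(ped), M)
  ref <- alt <- character(M)
  for (j in seq_len(M)) {
    obs <- c(rbind(a1[, j], a2[, j]))
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2L) {
      stop("more than two alleles at variant ", map$id[j])
    }
    ref[j] <- if (length(seen) >= 1L) seen[1] else "N"
    alt[j] <- if (length(seen) == 2L) seen[2] else "N"
    d <- (a1[, j] != ref[j]) + (a2[, j] != ref[j])
    d[is.na(a1[, j]) | is.na(a2[, j])] <- NA
    calls[, j] <- as.integer(d)
  }
  variants <- data.frame(chrom = map$chrom, pos_bp = map$pos_bp, id = map$id,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, variants)
}

## ---------------------------------------------------------------------------
## Genetic map

#' Genetic map objects
#'
#' A genetic map holds, per chromosome, sorted `(pos_bp, cM)` anchor pairs
#' plus a fallback constant rate (cM/Mb) used outside the anchored range.
#' [constant_rate_map()] builds an anchor-free map that applies the constant
#' rate everywhere, on any chromosome.
#'
#' @param anchors Named list (by chromosome) of `data.frame(pos_bp, cm)`.
#' @param fallback_rate_cm_mb Constant rate in cM/Mb applied beyond terminal
#'   anchors (and everywhere for a constant-rate map).
#' @param any_chrom If `TRUE` the map answers for any chromosome label.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors = list(), fallback_rate_cm_mb = 1,
                        any_chrom = length(anchors) == 0L) {
  stopifnot(fallback_rate_cm_mb >= 0)
  for (ch in names(anchors)) {
    a <- anchors[[ch]]
    stopifnot(all(c("pos_bp", "cm") %in% names(a)))
    a <- a[order(a$pos_bp), c("pos_bp", "cm")]
    if (is.unsorted(a$cm)) stop("cM not non-decreasing on chromosome ", ch)
    anchors[[ch]] <- a
  }
  structure(list(anchors = anchors, rate = fallback_rate_cm_mb,
                 any_chrom = any_chrom),
            class = "genetic_map")
}

#' @rdname genetic_map
#' @export
constant_rate_map <- function(fallback_rate_cm_mb = 1) {
  genetic_map(list(), fallback_rate_cm_mb, any_chrom = TRUE)
}

#' Read a HapMap-style genetic map TSV
#'
#' Expects a header line with columns `chrom`, `pos_bp`, `rate_cM_per_Mb`,
#' `map_cM`.
#'
#' @param path Path to the TSV file.
#' @param fallback_rate_cm_mb Rate used beyond the terminal anchors; defaults
#'   to the mean of the `rate_cM_per_Mb` column.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, fallback_rate_cm_mb = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "rate_cM_per_Mb", "map_cM")
  if (!all(need %in% names(tab))) {
    stop("genetic map must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(fallback_rate_cm_mb)) {
    fallback_rate_cm_mb <- mean(tab$rate_cM_per_Mb)
  }
  anchors <- lapply(split(tab, as.character(tab$chrom)), function(d) {
    data.frame(pos_bp = d$pos_bp, cm = d$map_cM)
  })
  genetic_map(anchors, fallback_rate_cm_mb)
}

.map_cm_at <- function(map, chrom, pos) {
  chrom <- as.character(chrom)
  if (!chrom %in% names(map$anchors)) {
    if (!map$any_chrom) stop("unknown chromosome in genetic map: ", chrom)
    return(pos / 1e6 * map$rate)
  }
  a <- map$anchors[[chrom]]
  cm <- numeric(length(pos))
  lo <- pos < a$pos_bp[1]
  hi <- pos > a$pos_bp[nrow(a)]
  mid <- !lo & !hi
  if (any(mid)) {
    cm[mid] <- stats::approx(a$pos_bp, a$cm, xout = pos[mid], ties = "ordered")$y
  }
  if (any(lo)) cm[lo] <- a$cm[1] - (a$pos_bp[1] - pos[lo]) / 1e6 * map$rate
  if (any(hi)) cm[hi] <- a$cm[nrow(a)] + (pos[hi] - a$pos_bp[nrow(a)]) / 1e6 * map$rate
  cm
}

#' Genetic length of a physical interval
#'
#' Linear interpolation between map anchors; beyond the terminal anchors the
#' fallback constant rate extends the map. Additive over adjacent intervals
#' and monotone in interval size.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label.
#' @param start_bp,end_bp 1-based interval endpoints, `start_bp <= end_bp`.
#' @return Genetic length in Morgans (>= 0).
#' @export
genetic_length <- function(map, chrom, start_bp, end_bp) {
  stopifnot(inherits(map, "genetic_map"), start_bp <= end_bp)
  cm <- .map_cm_at(map, chrom, c(start_bp, end_bp))
  max(0, (cm[2] - cm[1]) / 100)
}

## ---------------------------------------------------------------------------
## Sample sheet

#' Read / write a sample sheet
#'
#' Tab-separated table with columns `sample`, `role` (`carrier` or
#' `control`) and `population`.
#'
#' @param path File path.
#' @return A `data.frame` with the three columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("sample", "role", "population")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(sheet$role %in% c("carrier", "control"))) {
    stop("role must be 'carrier' or 'control'")
  }
  if (anyDuplicated(sheet$sample)) stop("duplicated sample in sheet")
  sheet[, need]
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check a sample sheet against a genotype or haplotype matrix
#'
#' Every matrix sample must appear exactly once in the sheet.
#' @param sheet Sample sheet `data.frame`.
#' @param x A `genotype_matrix` or `haplotype_matrix`.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_sheet <- function(sheet, x) {
  missing <- setdiff(x$samples, sheet$sample)
  if (length(missing)) {
    stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
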