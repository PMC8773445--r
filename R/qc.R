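## Quality-control stack: missingness, exact Hardy-Weinberg, MAF,
## sliding-window LD pruning. Filter order is missingness -> HWE -> MAF -> LD
## and every threshold actually applied is recorded in the QC report.

#' QC thresholds
#'
#' Container for the thresholds of the QC stack. Defaults mirror common
#' array practice: per-variant and per-sample missingness below 0.05,
#' family-wise Hardy-Weinberg alpha 0.05 with Bonferroni correction over the
#' tested variants, minor allele frequency at least 0.01, and LD pruning in
#' sliding windows of 50 SNPs moving by 5 with an r-squared threshold of 0.1.
#'
#' @param max_variant_missing,max_sample_missing Maximum tolerated
#'   missingness proportions (calls are kept when strictly below).
#' @param hwe_alpha Family-wise alpha for the exact Hardy-Weinberg test; the
#'   realized per-variant threshold is `hwe_alpha / n_variants_tested`.
#' @param min_maf Variants with minor allele frequency strictly below this
#'   are removed.
#' @param ld_window,ld_step,ld_r2 Sliding-window LD pruning parameters
#'   (window and step in SNP counts).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_variant_missing = 0.05,
                          max_sample_missing = 0.05,
                          hwe_alpha = 0.05,
                          min_maf = 0.01,
                          ld_window = 50L, ld_step = 5L, ld_r2 = 0.1) {
  stopifnot(max_variant_missing >= 0, max_variant_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            hwe_alpha > 0, hwe_alpha <= 1,
            min_maf >= 0, min_maf <= 1,
            ld_window >= ld_step, ld_step >= 1, ld_r2 >= 0, ld_r2 <= 1)
  structure(list(max_variant_missing = max_variant_missing,
                 max_sample_missing = max_sample_missing,
                 hwe_alpha = hwe_alpha, min_maf = min_maf,
                 ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2 = ld_r2),
            class = "qc_thresholds")
}

.gm_subset <- function(gm, keep_samples = NULL, keep_variants = NULL) {
  calls <- gm$calls
  samples <- gm$samples
  variants <- gm$variants
  if (!is.null(keep_variants)) {
    calls <- calls[, keep_variants, drop = FALSE]
    variants <- variants[keep_variants, , drop = FALSE]
  }
  if (!is.null(keep_samples)) {
    calls <- calls[keep_samples, , drop = FALSE]
    samples <- samples[keep_samples]
  }
  genotype_matrix(calls, samples, variants)
}

.qc_step <- function(name, removed_variants = 0L, removed_samples = 0L,
                     detail = list()) {
  c(list(step = name, removed_variants = removed_variants,
         removed_samples = removed_samples), detail)
}

#' Filter by missingness
#'
#' Variants are filtered first (missingness across samples), then samples
#' (missingness across the retained variants); each is kept only when its
#' missingness proportion is strictly below the threshold.
#'
#' @param gm A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `gm` (filtered matrix) and `report` (single-step QC
#'   report entry).
#' @export
filter_missingness <- function(gm, thresholds = qc_thresholds()) {
  vmiss <- colMeans(is.na(gm$calls))
  keep_v <- vmiss < thresholds$max_variant_missing
  gm2 <- .gm_subset(gm, keep_variants = keep_v)
  if (n_variants(gm2) == 0L) stop("no variants survive the missingness filter")
  smiss <- rowMeans(is.na(gm2$calls))
  keep_s <- smiss < thresholds$max_sample_missing
  gm3 <- .gm_subset(gm2, keep_samples = keep_s)
  if (n_samples(gm3) == 0L) stop("no samples survive the missingness filter")
  rep <- .qc_step("missingness",
                  removed_variants = sum(!keep_v),
                  removed_samples = sum(!keep_s),
                  detail = list(max_variant_missing = thresholds$max_variant_missing,
                                max_sample_missing = thresholds$max_sample_missing))
  list(gm = gm3, report = rep)
}

#' Exact Hardy-Weinberg test from genotype counts
#'
#' Two-sided exact test conditioning on the allele counts: the p-value is the
#' sum of the conditional probabilities of every heterozygote count (with the
#' same allele totals) whose probability does not exceed that of the observed
#' count. No mid-p adjustment is applied. Monomorphic sites return 1 by
#' convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer genotype counts,
#'   totalling at least one observation.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1L) stop("at least one observation required")
  n_a <- 2L * n_hom_ref + n_het
  n_b <- 2L * n_hom_alt + n_het
  if (n_a == 0L || n_b == 0L) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  lp <- lfactorial(n) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with allele totals")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

.hwe_pvalues <- function(gm) {
  c0 <- colSums(gm$calls == 0L, na.rm = TRUE)
  c1 <- colSums(gm$calls == 1L, na.rm = TRUE)
  c2 <- colSums(gm$calls == 2L, na.rm = TRUE)
  vapply(seq_len(n_variants(gm)),
         function(j) hwe_exact_test(c0[j], c1[j], c2[j]), numeric(1))
}

#' Hardy-Weinberg filter with Bonferroni correction
#'
#' Removes variants whose exact-test p-value falls strictly below
#' `hwe_alpha / n_variants_tested`; the realized threshold is reported.
#'
#' @inheritParams filter_missingness
#' @return List with `gm` and `report` (which records
#'   `realized_threshold`).
#' @export
hwe_filter <- function(gm, thresholds = qc_thresholds()) {
  pv <- .hwe_pvalues(gm)
  thr <- thresholds$hwe_alpha / n_variants(gm)
  keep <- pv >= thr
  gm2 <- .gm_subset(gm, keep_variants = keep)
  if (n_variants(gm2) == 0L) stop("no variants survive the HWE filter")
  rep <- .qc_step("hwe", removed_variants = sum(!keep),
                  detail = list(hwe_alpha = thresholds$hwe_alpha,
                                n_tested = n_variants(gm),
                                realized_threshold = thr))
  list(gm = gm2, report = rep)
}

#' Minor-allele-frequency filter
#'
#' MAF is computed on non-missing calls; variants with MAF strictly lower
#' than `min_maf` are removed (a variant at exactly the threshold is kept).
#'
#' @inheritParams filter_missingness
#' @return List with `gm` and `report`.
#' @export
maf_filter <- function(gm, thresholds = qc_thresholds()) {
  f <- colMeans(gm$calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep <- maf >= thresholds$min_maf
  gm2 <- .gm_subset(gm, keep_variants = keep)
  if (n_variants(gm2) == 0L) stop("no variants survive the MAF filter")
  rep <- .qc_step("maf", removed_variants = sum(!keep),
                  detail = list(min_maf = thresholds$min_maf))
  list(gm = gm2, report = rep)
}

.dosage_maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}

#' Sliding-window LD pruning
#'
#' Greedy pruning on genotype-dosage correlation: windows of `ld_window`
#' SNPs advance by `ld_step` along each chromosome; within a window, pairs
#' of still-kept variants with r-squared above `ld_r2` are resolved by
#' removing the member with the lower MAF (ties: the later variant in
#' position order). No surviving within-window pair exceeds the threshold.
#' r-squared is computed on 0/1/2 dosages with pairwise-complete
#' observations; pairs with undefined correlation (zero variance) are left
#' alone.
#'
#' @inheritParams filter_missingness
#' @return List with `kept_ids` (IDs of surviving variants), `gm` (matrix
#'   restricted to them) and `report`.
#' @export
ld_prune <- function(gm, thresholds = qc_thresholds()) {
  w <- thresholds$ld_window
  s <- thresholds$ld_step
  r2max <- thresholds$ld_r2
  maf <- .dosage_maf(gm$calls)
  keep <- rep(TRUE, n_variants(gm))
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    m <- length(idx)
    if (m < 2L) next
    start <- 1L
    repeat {
      stop_at <- min(start + w - 1L, m)
      win <- idx[start:stop_at]
      win <- win[keep[win]]
      if (length(win) >= 2L) {
        cc <- suppressWarnings(
          stats::cor(gm$calls[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))
        alive <- rep(TRUE, length(win))
        for (i in seq_len(length(win) - 1L)) {
          if (!alive[i]) next
          for (j in seq((i + 1L), length(win))) {
            if (!alive[j]) next
            r2 <- cc[i, j]^2
            if (!is.na(r2) && r2 > r2max) {
              vi <- win[i]; vj <- win[j]
              drop_j <- maf[vj] < maf[vi] ||
                (maf[vj] == maf[vi])  # equal MAF: drop the later variant
              if (drop_j) alive[j] <- FALSE else { alive[i] <- FALSE; break }
            }
          }
        }
        keep[win[!alive]] <- FALSE
      }
      if (stop_at >= m) break
      start <- start + s
    }
  }
  gm2 <- .gm_subset(gm, keep_variants = keep)
  rep <- .qc_step("ld_prune", removed_variants = sum(!keep),
                  detail = list(ld_window = w, ld_step = s, ld_r2 = r2max))
  list(kept_ids = gm$variants$id[keep], gm = gm2, report = rep)
}

#' Run the full QC stack
#'
#' Applies, in order: missingness, Hardy-Weinberg, MAF, LD pruning. The
#' ordered per-filter removal counts and the final dimensions are collected
#' into a QC report. The stack is a pure function of its inputs: the same
#' matrix and thresholds always produce the identical report.
#'
#' @inheritParams filter_missingness
#' @param prune Apply the LD-pruning step (set `FALSE` to keep the unpruned
#'   post-QC set, e.g. for segment analyses).
#' @return List with `gm` (the QC-passed matrix) and `report` (class
#'   `qc_report`).
#' @export
run_qc <- function(gm, thresholds = qc_thresholds(), prune = TRUE) {
  dims0 <- c(samples = n_samples(gm), variants = n_variants(gm))
  steps <- list()
  st <- filter_missingness(gm, thresholds)
  steps <- c(steps, list(st$report))
  st <- hwe_filter(st$gm, thresholds)
  steps <- c(steps, list(st$report))
  st <- maf_filter(st$gm, thresholds)
  steps <- c(steps, list(st$report))
  if (prune) {
    st <- ld_prune(st$gm, thresholds)
    steps <- c(steps, list(st$report))
  }
  gm_final <- st$gm
  report <- structure(
    list(initial = dims0,
         final = c(samples = n_samples(gm_final),
                   variants = n_variants(gm_final)),
         steps = steps),
    class = "qc_report")
  stopifnot(dims0["variants"] - sum(vapply(steps, `[[`, 0L, "removed_variants")) ==
              n_variants(gm_final))
  list(gm = gm_final, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d x %d -> %d x %d (samples x variants)\n",
              x$initial["samples"], x$initial["variants"],
              x$final["samples"], x$final["variants"]))
  for (s in x$steps) {
    cat(sprintf("  %-12s removed %d variant(s), %d sample(s)\n",
                s$step, s$removed_variants, s$removed_samples))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
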