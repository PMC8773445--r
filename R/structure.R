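## Genotype-based population structure and relatedness: PCA on scaled
## dosages, method-of-moments genome-wide IBD (Z0/Z1/Z2, PI_HAT) and the
## empirical top-percentile patient-patient relatedness screen.

#' Principal component analysis of genotype dosages
#'
#' Variants are mean-centred and scaled by `sqrt(p(1-p))` with `p` the
#' alt-allele frequency; missing calls are mean-imputed per variant (and the
#' imputation count reported); monomorphic variants are dropped. Components
#' come from the eigendecomposition of the sample-sample covariance of the
#' scaled matrix. Coordinates are defined up to sign, and are invariant (up
#' to sign) to sample-order permutation.
#'
#' @param gm A (typically LD-pruned) `genotype_matrix`.
#' @param k Number of components to return (`k < n_samples`).
#' @return An object of class `pca_result`: `scores` (samples x k,
#'   eigenvector coordinates scaled by the square root of the eigenvalue),
#'   `explained` (non-increasing explained-variance fractions),
#'   `n_imputed`, `n_dropped_monomorphic`.
#' @export
run_pca <- function(gm, k = 10L) {
  k <- as.integer(k)
  if (k >= n_samples(gm)) stop("k must be smaller than the sample count")
  X <- gm$calls
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.nan(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0L) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      X[is.na(X[, j]), j] <- 2 * p[j]
    }
  }
  Xs <- sweep(X, 2L, 2 * p, "-")
  Xs <- sweep(Xs, 2L, sqrt(p * (1 - p)), "/")
  G <- tcrossprod(Xs) / ncol(Xs)
  eig <- eigen(G, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  dimnames(scores) <- list(gm$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 explained = vals / sum(vals),
                 n_imputed = n_imputed,
                 n_dropped_monomorphic = sum(!poly)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (PC1 %.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1]))
  invisible(x)
}

.allele_freqs <- function(gm) {
  f <- colMeans(gm$calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  f
}

.ibd_terms <- function(p) {
  q <- 1 - p
  list(e0 = 2 * p^2 * q^2,                    # P(IBS0 | IBD0)
       e1_0 = 4 * p^3 * q + 4 * p * q^3,      # P(IBS1 | IBD0)
       e2_0 = p^4 + q^4 + 4 * p^2 * q^2,      # P(IBS2 | IBD0)
       e1_1 = 2 * p * q,                      # P(IBS1 | IBD1)
       e2_1 = 1 - 2 * p * q)                  # P(IBS2 | IBD1)
}

#' Method-of-moments genome-wide IBD for a sample pair
#'
#' Plug-in method of moments in the style of the classical `--genome`
#' analysis: observed identity-by-state counts are matched to their
#' expectations given the allele frequencies, inverting to the probabilities
#' `Z0`, `Z1`, `Z2` of sharing 0/1/2 alleles identical by descent. Estimates
#' are clamped to `[0, 1]` and renormalised to sum to one;
#' `PI_HAT = Z1/2 + Z2`. Only polymorphic variants with complete calls for
#' the pair contribute.
#'
#' @param gm A `genotype_matrix` (allele frequencies are estimated from the
#'   full sample set unless `freqs` is supplied).
#' @param pair Character vector of two distinct sample IDs.
#' @param freqs Optional per-variant alt-allele frequencies.
#' @param min_informative Warn when fewer informative variants remain.
#' @return A one-row `data.frame`: `id1`, `id2`, `Z0`, `Z1`, `Z2`,
#'   `PI_HAT`, `n_used`.
#' @export
ibd_moments <- function(gm, pair, freqs = NULL, min_informative = 100L) {
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("pair must name two distinct samples")
  }
  i <- match(pair, gm$samples)
  if (anyNA(i)) stop("unknown sample(s): ", paste(pair[is.na(i)], collapse = ", "))
  if (is.null(freqs)) freqs <- .allele_freqs(gm)
  terms <- .ibd_terms(freqs)
  g1 <- gm$calls[i[1], ]
  g2 <- gm$calls[i[2], ]
  ok <- !is.na(g1) & !is.na(g2) & freqs > 0 & freqs < 1
  m <- sum(ok)
  if (m == 0L) stop("no informative variants for pair ", pair[1], "/", pair[2])
  if (m < min_informative) {
    warning("only ", m, " informative variants for pair ",
            pair[1], "/", pair[2])
  }
  d <- abs(g1[ok] - g2[ok])
  N0 <- sum(d == 2L); N1 <- sum(d == 1L); N2 <- sum(d == 0L)
  e0 <- sum(terms$e0[ok]); e1_0 <- sum(terms$e1_0[ok])
  e2_0 <- sum(terms$e2_0[ok]); e1_1 <- sum(terms$e1_1[ok])
  e2_1 <- sum(terms$e2_1[ok])
  z0 <- N0 / e0
  z1 <- (N1 - z0 * e1_0) / e1_1
  z2 <- (N2 - z0 * e2_0 - z1 * e2_1) / m
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  data.frame(id1 = pair[1], id2 = pair[2],
             Z0 = z[1], Z1 = z[2], Z2 = z[3],
             PI_HAT = z[2] / 2 + z[3], n_used = m,
             stringsAsFactors = FALSE)
}

#' IBD estimates for a set of sample pairs
#'
#' @param gm A `genotype_matrix`.
#' @param pairs Two-column matrix or `data.frame` of sample IDs; default all
#'   unordered pairs.
#' @param ... Passed to [ibd_moments()].
#' @return `data.frame` with one row per pair, mirroring the classical
#'   genome-file columns (`id1`, `id2`, `Z0`, `Z1`, `Z2`, `PI_HAT`).
#' @export
ibd_pairs <- function(gm, pairs = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- t(utils::combn(gm$samples, 2L))
  }
  pairs <- as.matrix(pairs)
  freqs <- .allele_freqs(gm)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    ibd_moments(gm, pairs[r, ], freqs = freqs, ...)
  })
  do.call(rbind, out)
}

#' Relatedness screen against the patient-control empirical distribution
#'
#' Computes `PI_HAT` for every patient-patient and patient-control pair and
#' flags any patient-patient value exceeding the empirical 99th percentile
#' (nearest-rank, i.e. the `ceiling(0.99 n)`-th order statistic) of the
#' patient-control values. A cohort of unrelated families is expected to
#' produce no flags.
#'
#' @param gm A `genotype_matrix`.
#' @param sheet Sample sheet with `carrier` / `control` roles; the control
#'   set used for the empirical distribution is exactly the sheet's
#'   controls.
#' @param top_quantile Flagging quantile (default 0.99).
#' @param ... Passed to [ibd_moments()].
#' @return An object of class `relatedness_verdict`: `verdicts` (per
#'   patient-patient pair: `PI_HAT`, its quantile within the
#'   patient-control distribution, `flagged`), `threshold`, and
#'   `patient_control` (the full patient-control IBD table).
#' @export
relatedness_screen <- function(gm, sheet, top_quantile = 0.99, ...) {
  validate_sheet(sheet, gm)
  carriers <- sheet$sample[sheet$role == "carrier"]
  controls <- sheet$sample[sheet$role == "control"]
  carriers <- intersect(gm$samples, carriers)
  controls <- intersect(gm$samples, controls)
  if (length(carriers) < 2L) stop("need at least 2 carriers")
  if (length(controls) < 10L) {
    stop("need at least 10 controls, got ", length(controls))
  }
  pc_pairs <- expand.grid(id1 = carriers, id2 = controls,
                          stringsAsFactors = FALSE)
  pc <- ibd_pairs(gm, pc_pairs, ...)
  pp <- ibd_pairs(gm, t(utils::combn(carriers, 2L)), ...)
  sorted <- sort(pc$PI_HAT)
  thr <- sorted[ceiling(top_quantile * length(sorted))]
  verdicts <- data.frame(
    id1 = pp$id1, id2 = pp$id2, PI_HAT = pp$PI_HAT,
    quantile = vapply(pp$PI_HAT, function(v) mean(pc$PI_HAT <= v), numeric(1)),
    flagged = pp$PI_HAT > thr,
    stringsAsFactors = FALSE)
  structure(list(verdicts = verdicts, threshold = thr,
                 top_quantile = top_quantile, patient_control = pc),
            class = "relatedness_verdict")
}

#' @export
print.relatedness_verdict <- function(x, ...) {
  nf <- sum(x$verdicts$flagged)
  cat(sprintf(
    "relatedness screen: %d patient-patient pair(s), threshold PI_HAT > %.4f (top %.0f%%), %d flagged\n",
    nrow(x$verdicts), x$threshold, 100 * (1 - x$top_quantile), nf))
  invisible(x)
}
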