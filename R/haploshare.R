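## Shared-haplotype detection around a focal mutation and its empirical
## significance: maximal identical segments for a set of haplotypes,
## genome-wide rank statistics for the same member set, and the
## patient-control sharing null.
##
## Missing-data rule (default): a missing allele never breaks a segment but
## does not count towards its SNP total. The strict alternative (missing
## breaks identity) is available via `missing_matches = FALSE`.

#' Specify the focal mutation and its carriers
#'
#' @param chrom Chromosome of the focal variant.
#' @param pos_bp 1-based position of the focal variant.
#' @param carriers Character vector of carrier sample IDs.
#' @param risk_allele Allele (0 or 1) tagging the mutation on the shared
#'   haplotype; the risk allele is always named explicitly, no
#'   ancestral/derived inference is attempted.
#' @return An object of class `focal_spec`.
#' @export
focal_spec <- function(chrom, pos_bp, carriers, risk_allele = 1L) {
  stopifnot(length(carriers) >= 1L, risk_allele %in% c(0L, 1L))
  structure(list(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                 carriers = as.character(carriers),
                 risk_allele = as.integer(risk_allele)),
            class = "focal_spec")
}

.focal_index <- function(hm, spec) {
  j <- which(hm$variants$chrom == spec$chrom & hm$variants$pos_bp == spec$pos_bp)
  if (length(j) != 1L) {
    stop("focal site ", spec$chrom, ":", spec$pos_bp,
         " not found in the variant list")
  }
  j
}

#' Select the risk-bearing haplotype of each carrier
#'
#' For each carrier, picks the haplotype carrying the risk allele at the
#' focal site. A homozygous carrier contributes its phase-0 haplotype (the
#' deterministic tie rule; see `try_both_phases` in
#' [focal_shared_segment()] for the alternative). A carrier whose focal call
#' is missing on one phase only is assigned the missing phase (the missing
#' allele may be the risk allele), with a warning.
#'
#' @param hm A `haplotype_matrix`.
#' @param spec A [focal_spec()].
#' @return Named integer vector of haplotype row indices (names are
#'   haplotype IDs), one per carrier.
#' @export
carrier_haplotypes <- function(hm, spec) {
  j <- .focal_index(hm, spec)
  rows <- integer(0)
  for (s in spec$carriers) {
    si <- match(s, hm$samples)
    if (is.na(si)) stop("carrier not in matrix: ", s)
    r0 <- 2L * si - 1L
    r1 <- 2L * si
    a <- hm$alleles[c(r0, r1), j]
    is_risk <- !is.na(a) & a == spec$risk_allele
    if (all(is.na(a))) {
      stop("focal site not genotyped for carrier ", s)
    }
    if (is_risk[1]) {
      pick <- r0                       # phase-0 tie rule covers homozygotes
    } else if (is_risk[2]) {
      pick <- r1
    } else if (anyNA(a)) {
      pick <- if (is.na(a[1])) r0 else r1
      warning("carrier ", s, ": focal allele missing on the selected phase")
    } else {
      stop("carrier ", s, " does not carry the risk allele at the focal site")
    }
    rows <- c(rows, pick)
  }
  names(rows) <- rownames(hm$alleles)[rows]
  rows
}

## Per-site agreement of a set of haplotype rows.
## Returns agree (segment-continuation rule) and counted (contributes to
## n_snps: all members non-missing and identical).
.agreement <- function(hm, members, missing_matches = TRUE) {
  rows <- lapply(members, function(r) hm$alleles[r, ])
  cmin <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), rows)
  cmax <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), rows)
  complete <- !Reduce(`|`, lapply(rows, is.na))
  equal <- cmin == cmax
  counted <- complete & !is.na(equal) & equal
  if (missing_matches) {
    agree <- equal
    agree[is.na(agree)] <- TRUE        # all-missing site matches
  } else {
    agree <- counted
  }
  list(agree = agree, counted = counted)
}

.members_label <- function(hm, members) {
  paste(rownames(hm$alleles)[members], collapse = ",")
}

.segments_from_runs <- function(hm, ag, members, keep_empty = FALSE) {
  v <- hm$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    r <- rle(ag$agree[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tr <- r$values
    if (!any(tr)) next
    gs <- idx[starts[tr]]                # global start index per TRUE run
    ge <- idx[ends[tr]]
    cs <- c(0L, cumsum(ag$counted[idx]))
    n_snps <- cs[ends[tr] + 1L] - cs[starts[tr]]
    if (!keep_empty) {
      ok <- n_snps > 0L
      gs <- gs[ok]; ge <- ge[ok]; n_snps <- n_snps[ok]
    }
    if (!length(gs)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      start_bp = v$pos_bp[gs], end_bp = v$pos_bp[ge],
      start_idx = gs, end_idx = ge, n_snps = as.integer(n_snps),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    seg <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), start_idx = integer(0),
                      end_idx = integer(0), n_snps = integer(0))
  } else {
    seg <- do.call(rbind, out)
  }
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$members <- rep(.members_label(hm, members), nrow(seg))
  seg
}

#' Maximal shared segment around the focal mutation
#'
#' Starting from the focal SNP, the segment extends left and right as long
#' as all selected carrier haplotypes agree (under the missing-data rule).
#' The result is maximal: extending one SNP in either direction breaks
#' identity. Endpoints are the outermost agreeing SNPs (1-based inclusive);
#' `length_bp = end_bp - start_bp`.
#'
#' @param hm A `haplotype_matrix`.
#' @param spec A [focal_spec()].
#' @param members Optional haplotype row indices to use instead of
#'   [carrier_haplotypes()] (e.g. a carrier subset, for the nested-segment
#'   analysis).
#' @param missing_matches Missing-data rule (see module header).
#' @param try_both_phases For homozygous carriers, try both phase choices
#'   and keep the combination giving the longest segment (by SNP count).
#' @return One-row segment `data.frame` (`chrom`, `start_bp`, `end_bp`,
#'   `start_idx`, `end_idx`, `n_snps`, `length_bp`, `members`).
#' @export
focal_shared_segment <- function(hm, spec, members = NULL,
                                 missing_matches = TRUE,
                                 try_both_phases = FALSE) {
  j <- .focal_index(hm, spec)
  if (is.null(members)) {
    members <- carrier_haplotypes(hm, spec)
    if (try_both_phases) {
      hom <- vapply(members, function(r) {
        other <- if (r %% 2L == 1L) r + 1L else r - 1L
        a <- hm$alleles[other, j]
        !is.na(a) && a == spec$risk_allele
      }, logical(1))
      if (any(hom)) {
        best <- NULL
        grid <- expand.grid(rep(list(c(FALSE, TRUE)), sum(hom)))
        for (g in seq_len(nrow(grid))) {
          mm <- members
          flip <- which(hom)[unlist(grid[g, ])]
          mm[flip] <- ifelse(mm[flip] %% 2L == 1L, mm[flip] + 1L, mm[flip] - 1L)
          seg_g <- focal_shared_segment(hm, spec, members = mm,
                                        missing_matches = missing_matches)
          if (is.null(best) || seg_g$n_snps > best$n_snps) best <- seg_g
        }
        return(best)
      }
    }
  }
  ag <- .agreement(hm, members, missing_matches)
  if (!ag$agree[j]) {
    warning("haplotypes disagree at the focal SNP itself; degenerate segment")
    v <- hm$variants
    return(data.frame(chrom = spec$chrom, start_bp = v$pos_bp[j],
                      end_bp = v$pos_bp[j], start_idx = j, end_idx = j,
                      n_snps = 1L, length_bp = 0L,
                      members = .members_label(hm, members),
                      stringsAsFactors = FALSE))
  }
  segs <- .segments_from_runs(hm, ag, members, keep_empty = TRUE)
  hit <- segs$start_idx <= j & segs$end_idx >= j & segs$chrom == spec$chrom
  segs[which(hit)[1], , drop = FALSE]
}

#' Pairwise focal sharing between all carrier pairs
#'
#' The per-pair analogue of [focal_shared_segment()]: for every pair of
#' carriers, the maximal segment around the focal site shared by their
#' risk-bearing haplotypes.
#'
#' @inheritParams focal_shared_segment
#' @return `data.frame` with one row per carrier pair (`sample1`, `sample2`
#'   plus the segment columns).
#' @export
pairwise_focal_segments <- function(hm, spec, missing_matches = TRUE) {
  members <- carrier_haplotypes(hm, spec)
  cs <- spec$carriers
  pairs <- utils::combn(seq_along(cs), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i1 <- pairs[1, k]; i2 <- pairs[2, k]
    seg <- focal_shared_segment(hm, spec, members = members[c(i1, i2)],
                                missing_matches = missing_matches)
    cbind(data.frame(sample1 = cs[i1], sample2 = cs[i2],
                     stringsAsFactors = FALSE), seg)
  })
  do.call(rbind, out)
}

#' Genome-wide scan for segments shared by a haplotype set
#'
#' Returns every distinct maximal interval over which all member haplotypes
#' agree: breakpoint-delimited runs of agreeing SNPs, one segment per run,
#' across all chromosomes. Runs containing no counted SNP (all-missing) are
#' dropped.
#'
#' @param hm A `haplotype_matrix`.
#' @param members Haplotype row indices (>= 2).
#' @param missing_matches Missing-data rule.
#' @return Segment `data.frame` (possibly zero rows), columns as in
#'   [focal_shared_segment()].
#' @export
genomewide_segment_scan <- function(hm, members, missing_matches = TRUE) {
  if (length(members) < 2L) stop("need at least 2 member haplotypes")
  ag <- .agreement(hm, members, missing_matches)
  .segments_from_runs(hm, ag, members)
}

#' Empirical genome-wide rank of the focal segment
#'
#' Ranks the focal segment against the genome-wide distribution of distinct
#' segments shared by the same member set, in both the SNP-count and bp
#' metrics: `p = (1 + n_other_segments >= focal) / n_total`, so the focal
#' segment always counts itself and `p` is never 0.
#'
#' @param focal One-row segment `data.frame` from [focal_shared_segment()].
#' @param scan Segment `data.frame` from [genomewide_segment_scan()] for the
#'   same member set.
#' @param exclude_radius_bp Optionally drop from the null all segments on
#'   the focal chromosome overlapping this radius around the focal segment
#'   (default 0: only the focal segment itself is removed from the
#'   comparison set).
#' @return `data.frame` with one row per metric (`snps`, `bp`): focal value,
#'   `n_ge` (comparable segments at least as large, focal included),
#'   `n_total`, `p`.
#' @export
rank_statistics <- function(focal, scan, exclude_radius_bp = 0) {
  if (nrow(scan) == 0L) stop("empty genome-wide scan")
  is_focal <- scan$chrom == focal$chrom &
    scan$start_idx == focal$start_idx & scan$end_idx == focal$end_idx
  others <- scan[!is_focal, , drop = FALSE]
  if (exclude_radius_bp > 0) {
    drop <- others$chrom == focal$chrom &
      others$end_bp >= focal$start_bp - exclude_radius_bp &
      others$start_bp <= focal$end_bp + exclude_radius_bp
    others <- others[!drop, , drop = FALSE]
  }
  total <- nrow(others) + 1L
  mk <- function(metric, fv, ov) {
    n_ge <- 1L + sum(ov >= fv)
    data.frame(metric = metric, focal_value = fv, n_ge = n_ge,
               n_total = total, p = n_ge / total, stringsAsFactors = FALSE)
  }
  rbind(mk("snps", focal$n_snps, others$n_snps),
        mk("bp", focal$length_bp, others$length_bp))
}

#' Patient-control sharing null for the focal segment size
#'
#' For each carrier, the risk-bearing haplotype is compared genome-wide with
#' every control haplotype (both phases); the scan counts distinct shared
#' segments at least as large as the target (SNP count and bp length
#' metrics). The per-patient empirical p-value is `count / total` over all
#' segments examined for that patient; a zero count is reported as the
#' one-sided bound `1 / (total + 1)`. The Bonferroni-corrected threshold
#' `alpha / (n_patients * n_controls)` is reported alongside.
#'
#' @param hm A `haplotype_matrix`.
#' @param spec A [focal_spec()].
#' @param controls Character vector of control sample IDs.
#' @param target_snps,target_bp Target segment size in the two metrics
#'   (typically the focal segment's `n_snps` and `length_bp`).
#' @param alpha Family-wise alpha for the Bonferroni threshold.
#' @param missing_matches Missing-data rule.
#' @return An object of class `control_null_result`: `per_patient`
#'   `data.frame` (`sample`, `n_ge_snps`, `n_ge_bp`, `n_total`, `p_snps`,
#'   `p_bp`, `zero_bound_snps`, `zero_bound_bp`), plus `bonferroni`,
#'   `n_tests`, `alpha`.
#' @export
patient_control_null <- function(hm, spec, controls, target_snps, target_bp,
                                 alpha = 0.05, missing_matches = TRUE) {
  if (length(controls) < 1L) stop("need at least one control")
  members <- carrier_haplotypes(hm, spec)
  ctrl_idx <- match(controls, hm$samples)
  if (anyNA(ctrl_idx)) {
    stop("unknown control(s): ", paste(controls[is.na(ctrl_idx)], collapse = ", "))
  }
  ctrl_rows <- c(rbind(2L * ctrl_idx - 1L, 2L * ctrl_idx))
  rows_out <- lapply(seq_along(spec$carriers), function(i) {
    n_ge_snps <- 0L; n_ge_bp <- 0L; n_total <- 0L
    for (cr in ctrl_rows) {
      segs <- genomewide_segment_scan(hm, c(members[i], cr), missing_matches)
      n_total <- n_total + nrow(segs)
      n_ge_snps <- n_ge_snps + sum(segs$n_snps >= target_snps)
      n_ge_bp <- n_ge_bp + sum(segs$length_bp >= target_bp)
    }
    data.frame(sample = spec$carriers[i],
               n_ge_snps = n_ge_snps, n_ge_bp = n_ge_bp, n_total = n_total,
               p_snps = if (n_ge_snps > 0L) n_ge_snps / n_total else 1 / (n_total + 1),
               p_bp = if (n_ge_bp > 0L) n_ge_bp / n_total else 1 / (n_total + 1),
               zero_bound_snps = n_ge_snps == 0L,
               zero_bound_bp = n_ge_bp == 0L,
               stringsAsFactors = FALSE)
  })
  n_tests <- length(spec$carriers) * length(controls)
  structure(list(per_patient = do.call(rbind, rows_out),
                 bonferroni = alpha / n_tests, n_tests = n_tests,
                 alpha = alpha,
                 target_snps = target_snps, target_bp = target_bp),
            class = "control_null_result")
}

#' @export
print.control_null_result <- function(x, ...) {
  cat(sprintf(
    "patient-control null: targets >= %d SNPs / %d bp; %d tests, Bonferroni threshold %.3g\n",
    x$target_snps, x$target_bp, x$n_tests, x$bonferroni))
  print(x$per_patient, row.names = FALSE)
  invisible(x)
}

#' Write segments as a BED-like TSV
#'
#' @param segments Segment `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("chrom", "start_bp", "end_bp", "n_snps", "length_bp", "members")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
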