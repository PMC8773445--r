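## Synthetic phased cohorts with a planted founder event.
##
## The generator emulates a small disease-cohort array study: a background
## population of phased haplotypes with short-range LD (first-order Markov
## copying from previously generated haplotypes), a rare focal risk allele
## absent from all background haplotypes, and a founder haplotype planted
## into the carriers over intervals eroded by recombination: each side of
## each carrier's interval is an independent Exponential(erosion_c * t_star)
## genetic distance from the focal site, matching the erosion model the
## tMRCA estimator inverts (erosion_c = 1 per lineage per side, so the
## pairwise consensus erodes at rate 2 t and the n-carrier consensus at
## rate n t).

#' Simulation configuration
#'
#' Defaults follow the study design the package targets, scaled down to
#' desk size: 84 controls and 7 carriers genotyped on a SNP array (array
#' density ~1 SNP / 6 kb), with the focal mutation on chromosome 21.
#'
#' @param n_controls,n_carriers Cohort composition.
#' @param n_snps SNPs per chromosome.
#' @param chrom_names Chromosome labels (their count sets the chromosome
#'   number).
#' @param bp_per_snp Mean physical spacing; chromosome length is
#'   `n_snps * bp_per_snp`.
#' @param beta_shape1,beta_shape2 Beta parameters of the background
#'   alt-allele frequency spectrum.
#' @param maf_floor Frequencies are rescaled into
#'   `[maf_floor, 1 - maf_floor]` (common-SNP array ascertainment).
#' @param copy_prob First-order Markov copying probability between adjacent
#'   sites: the chance that a haplotype keeps copying its current template
#'   at the next SNP. 0 removes LD; values near 1 give long perfectly
#'   correlated runs.
#' @param innovate_prob At a template switch, the probability of drawing
#'   from the site frequency instead of copying a previous haplotype.
#' @param founder_tmrca True age of the planted founder event, generations.
#' @param erosion_c Erosion rate multiplier per lineage per side (see module
#'   header).
#' @param focal_chrom,focal_frac Focal site: chromosome and relative SNP
#'   index along it.
#' @param missing_rate Per-call missingness rate applied by
#'   [sim_cohort()].
#' @param map_rate_cm_mb Constant genetic-map rate used to convert eroded
#'   genetic distances to bp.
#' @param homozygous_carriers Plant the founder segment on both phases of
#'   each carrier.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 84L, n_carriers = 7L,
                       n_snps = 2000L, chrom_names = c("21", "22"),
                       bp_per_snp = 6000L,
                       beta_shape1 = 2, beta_shape2 = 2, maf_floor = 0.05,
                       copy_prob = 0.9, innovate_prob = 0.15,
                       founder_tmrca = 50, erosion_c = 1,
                       focal_chrom = chrom_names[1], focal_frac = 0.5,
                       missing_rate = 0.01, map_rate_cm_mb = 1,
                       homozygous_carriers = FALSE) {
  stopifnot(n_controls >= 1L, n_carriers >= 1L, n_snps >= 10L,
            length(chrom_names) >= 1L, bp_per_snp >= 1L,
            founder_tmrca > 0, erosion_c > 0,
            copy_prob >= 0, copy_prob < 1,
            innovate_prob >= 0, innovate_prob <= 1,
            maf_floor > 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1,
            map_rate_cm_mb > 0,
            focal_chrom %in% chrom_names,
            focal_frac > 0, focal_frac < 1)
  if (beta_shape1 <= 0 || beta_shape2 <= 0) {
    stop("degenerate Beta frequency spectrum parameters")
  }
  structure(as.list(environment()), class = "sim_config")
}

.sim_samples <- function(config) {
  c(sprintf("C%03d", seq_len(config$n_controls)),
    sprintf("P%02d", seq_len(config$n_carriers)))
}

#' Sample sheet for a simulated cohort
#' @param config A [sim_config()].
#' @return Sample-sheet `data.frame` (controls then carriers).
#' @export
sim_sample_sheet <- function(config) {
  data.frame(sample = .sim_samples(config),
             role = rep(c("control", "carrier"),
                        c(config$n_controls, config$n_carriers)),
             population = "simulated", stringsAsFactors = FALSE)
}

.focal_global_index <- function(config) {
  chrom_i <- match(config$focal_chrom, config$chrom_names)
  local_j <- max(1L, min(config$n_snps,
                         as.integer(round(config$focal_frac * config$n_snps))))
  list(chrom_i = chrom_i, local_j = local_j)
}

#' Simulate the background cohort
#'
#' Per-site alt frequencies are drawn from the Beta spectrum; each
#' haplotype after the first is built as a Markov mosaic: at each SNP it
#' keeps its current template with probability `copy_prob`, otherwise it
#' switches to a new template (a uniformly chosen previously generated
#' haplotype, or an independent frequency draw with probability
#' `innovate_prob`). The focal site carries the reference allele in every
#' background haplotype: the risk allele enters only via
#' [plant_founder()].
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (generation is deterministic given
#'   (config, seed)).
#' @return A `haplotype_matrix`.
#' @export
simulate_background <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- .sim_samples(config)
  n_hap <- 2L * length(samples)
  M <- config$n_snps
  foc <- .focal_global_index(config)
  all_alleles <- list()
  all_variants <- list()
  for (ci in seq_along(config$chrom_names)) {
    ch <- config$chrom_names[ci]
    p <- config$maf_floor +
      (1 - 2 * config$maf_floor) * stats::rbeta(M, config$beta_shape1,
                                                config$beta_shape2)
    H <- matrix(0L, n_hap, M)
    H[1L, ] <- stats::rbinom(M, 1L, p)
    for (i in 2:n_hap) {
      switch_at <- stats::runif(M) < (1 - config$copy_prob)
      switch_at[1L] <- TRUE
      run_id <- cumsum(switch_at)
      nr <- run_id[M]
      innov <- stats::runif(nr) < config$innovate_prob
      src <- integer(nr)
      src[!innov] <- sample.int(i - 1L, sum(!innov), replace = TRUE)
      s <- src[run_id]
      h <- integer(M)
      new_draw <- s == 0L
      h[new_draw] <- stats::rbinom(sum(new_draw), 1L, p[new_draw])
      if (any(!new_draw)) {
        h[!new_draw] <- H[cbind(s[!new_draw], which(!new_draw))]
      }
      H[i, ] <- h
    }
    if (ci == foc$chrom_i) {
      H[, foc$local_j] <- 0L             # risk allele absent from background
      p[foc$local_j] <- 1 / (2 * n_hap)  # nominally rare
    }
    pos <- sort(sample.int(M * config$bp_per_snp, M))
    all_alleles[[ci]] <- H
    all_variants[[ci]] <- data.frame(
      chrom = ch, pos_bp = pos,
      id = sprintf("%s_snp%05d", ch, seq_len(M)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, all_variants)
  haplotype_matrix(do.call(cbind, all_alleles), samples, variants)
}

#' Focal-variant description for a simulated cohort
#' @param config A [sim_config()].
#' @param hm The simulated `haplotype_matrix`.
#' @return A [focal_spec()] naming the configured carriers.
#' @export
sim_focal_spec <- function(config, hm) {
  foc <- .focal_global_index(config)
  id <- sprintf("%s_snp%05d", config$focal_chrom, foc$local_j)
  j <- match(id, hm$variants$id)
  sheet <- sim_sample_sheet(config)
  focal_spec(config$focal_chrom, hm$variants$pos_bp[j],
             carriers = sheet$sample[sheet$role == "carrier"],
             risk_allele = 1L)
}

#' Plant a founder event into a background cohort
#'
#' Creates a founder haplotype bearing the risk allele at the focal site
#' (alleles drawn from the background frequencies, so it is unrelated to any
#' cohort haplotype outside the planted intervals). Each carrier receives
#' the founder alleles on one phase (chosen at random; both phases when
#' `homozygous_carriers`) over an interval whose two sides are independent
#' Exponential(`erosion_c * founder_tmrca`) genetic distances converted to
#' bp via the constant map rate. An interval that would contain no SNP is
#' resampled (retry count recorded; the focal SNP itself is always
#' contained). Controls never carry the risk allele.
#'
#' @param hm Background `haplotype_matrix` from [simulate_background()].
#' @param config The same [sim_config()].
#' @param seed Optional RNG seed.
#' @return List with `hm` (cohort with planted founder segments) and
#'   `truth` (class `founder_truth`): `t_star`, focal coordinates, the
#'   founder haplotype over the focal chromosome, per-carrier
#'   `data.frame` (`sample`, `phase`, `start_bp`, `end_bp`, `start_idx`,
#'   `end_idx`, `n_snps`), and `retries`.
#' @export
plant_founder <- function(hm, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sheet <- sim_sample_sheet(config)
  carriers <- sheet$sample[sheet$role == "carrier"]
  spec <- sim_focal_spec(config, hm)
  j <- .focal_index(hm, spec)
  chrom_cols <- which(hm$variants$chrom == spec$chrom)
  pos <- hm$variants$pos_bp[chrom_cols]
  ## founder alleles drawn from the realized cohort frequencies, so the
  ## founder haplotype has no LD with any cohort haplotype
  p_ch <- pmin(pmax(colMeans(hm$alleles[, chrom_cols, drop = FALSE],
                             na.rm = TRUE), 0.05), 0.95)
  founder <- stats::rbinom(length(chrom_cols), 1L, p_ch)
  founder[match(j, chrom_cols)] <- 1L
  rate_gen <- config$erosion_c * config$founder_tmrca   # per Morgan, per side
  morgans_to_bp <- function(d) d * 100 / config$map_rate_cm_mb * 1e6
  rows <- list()
  retries <- 0L
  alleles <- hm$alleles
  for (s in carriers) {
    si <- match(s, hm$samples)
    phases <- if (config$homozygous_carriers) c(0L, 1L) else
      sample(c(0L, 1L), 1L)
    for (ph in phases) {
      repeat {
        d_left <- stats::rexp(1, rate_gen)
        d_right <- stats::rexp(1, rate_gen)
        lo <- max(pos[1], spec$pos_bp - morgans_to_bp(d_left))
        hi <- min(pos[length(pos)], spec$pos_bp + morgans_to_bp(d_right))
        inside <- which(pos >= lo & pos <= hi)
        if (length(inside) >= 1L) break
        retries <- retries + 1L
      }
      row <- 2L * si - 2L + ph + 1L
      alleles[row, chrom_cols[inside]] <- founder[inside]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, phase = ph,
        start_bp = pos[inside[1]], end_bp = pos[inside[length(inside)]],
        start_idx = chrom_cols[inside[1]],
        end_idx = chrom_cols[inside[length(inside)]],
        n_snps = length(inside), stringsAsFactors = FALSE)
    }
  }
  hm2 <- haplotype_matrix(alleles, hm$samples, hm$variants)
  truth <- structure(list(t_star = config$founder_tmrca,
                          focal_chrom = spec$chrom, focal_pos = spec$pos_bp,
                          risk_allele = 1L,
                          founder_haplotype = founder,
                          carriers = do.call(rbind, rows),
                          retries = retries),
                     class = "founder_truth")
  list(hm = hm2, truth = truth)
}

#' Mask calls at random
#'
#' i.i.d. masking of haplotype alleles at the given rate; deterministic
#' given the seed.
#'
#' @param hm A `haplotype_matrix`.
#' @param rate Missingness rate in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @param protect_variants Variant column indices never masked (e.g. the
#'   focal site).
#' @return The masked `haplotype_matrix`.
#' @export
inject_missingness <- function(hm, rate, seed = NULL,
                               protect_variants = integer(0)) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(hm)
  if (!is.null(seed)) set.seed(seed)
  alleles <- hm$alleles
  mask <- matrix(stats::runif(length(alleles)) < rate, nrow(alleles))
  if (length(protect_variants)) mask[, protect_variants] <- FALSE
  alleles[mask] <- NA_integer_
  haplotype_matrix(alleles, hm$samples, hm$variants)
}

#' Simulate a full cohort
#'
#' Background + planted founder event (optional) + missingness, in one call
#' under one seed.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param plant Plant the founder event (set `FALSE` for a null cohort with
#'   no founder sharing; the carriers still exist but carry no risk
#'   haplotype).
#' @return List with `hm`, `truth` (`NULL` when `plant = FALSE`), `sheet`,
#'   `spec` (`focal_spec`; `NULL` when `plant = FALSE`) and `config`.
#' @export
sim_cohort <- function(config = sim_config(), seed = NULL, plant = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  hm <- simulate_background(config)
  truth <- NULL
  spec <- NULL
  if (plant) {
    planted <- plant_founder(hm, config)
    hm <- planted$hm
    truth <- planted$truth
    spec <- sim_focal_spec(config, hm)
  }
  if (config$missing_rate > 0) {
    protect <- if (plant) .focal_index(hm, spec) else integer(0)
    hm <- inject_missingness(hm, config$missing_rate,
                             protect_variants = protect)
  }
  list(hm = hm, truth = truth, sheet = sim_sample_sheet(config),
       spec = spec, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the phased VCF, sample sheet TSV, constant-rate genetic map TSV,
#' ground-truth JSON and a manifest; all files round-trip through the
#' package readers.
#'
#' @param cohort Result of [sim_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  config <- cohort$config
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             sheet = file.path(out_dir, "samples.tsv"),
             map = file.path(out_dir, "map.tsv"),
             truth = file.path(out_dir, "truth.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write_phased_vcf(cohort$hm, paths["vcf"])
  write_sample_sheet(cohort$sheet, paths["sheet"])
  v <- cohort$hm$variants
  map_rows <- do.call(rbind, lapply(split(v, v$chrom), function(d) {
    anchor <- c(d$pos_bp[1], d$pos_bp[nrow(d)])
    data.frame(chrom = d$chrom[1], pos_bp = anchor,
               rate_cM_per_Mb = config$map_rate_cm_mb,
               map_cM = anchor / 1e6 * config$map_rate_cm_mb)
  }))
  utils::write.table(map_rows, paths["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(unclass(cohort$truth), paths["truth"],
                         auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  manifest <- list(files = basename(unname(paths)),
                   config = unclass(config))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
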