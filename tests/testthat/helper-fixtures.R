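## Fixture builders and independent oracles shared across the test files.
## Everything is generated in code; no binary fixtures.

## quick variant table: one chromosome unless chrom given per-site
tv <- function(pos, chrom = "1") {
  data.frame(chrom = chrom, pos_bp = as.integer(pos),
             id = paste0(chrom, "_", pos), ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

## haplotype matrix straight from an allele matrix (rows = haplotypes)
make_hm <- function(alleles, pos = NULL, chrom = "1") {
  alleles <- as.matrix(alleles)
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 1000L
  haplotype_matrix(alleles, paste0("S", seq_len(nrow(alleles) / 2)),
                   tv(pos, chrom))
}

make_gm <- function(calls, pos = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  genotype_matrix(calls, paste0("S", seq_len(nrow(calls))), tv(pos, chrom))
}

## random phased fixture with optional missingness, possibly two chromosomes
random_hm <- function(n_hap, n_snps, miss = 0, two_chrom = FALSE) {
  al <- matrix(rbinom(n_hap * n_snps, 1L, runif(n_snps, 0.2, 0.8)[
    rep(seq_len(n_snps), each = n_hap)]), n_hap, n_snps)
  if (miss > 0) al[matrix(runif(length(al)) < miss, n_hap)] <- NA
  if (two_chrom) {
    half <- n_snps %/% 2L
    v <- rbind(tv(seq_len(half) * 997L, "1"),
               tv(seq_len(n_snps - half) * 1003L, "2"))
    haplotype_matrix(al, paste0("S", seq_len(n_hap / 2)), v)
  } else {
    make_hm(al)
  }
}

## ---------------------------------------------------------------------------
## Independent oracles

## exact HWE p-value by direct factorial enumeration (totals <= 50 keep
## factorial() exactly representable)
oracle_hwe <- function(a, b, c) {
  n <- a + b + c
  nA <- 2 * a + b
  nB <- 2 * c + b
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    cc <- (nB - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(cc)) * 2^h *
      factorial(nA) * factorial(nB) / factorial(2 * n)
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(b, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

## site-wise identity of a haplotype slice, computed independently of the
## package's pmin/pmax machinery
oracle_site_agrees <- function(hm, members, j, missing_matches) {
  a <- hm$alleles[members, j]
  obs <- a[!is.na(a)]
  if (length(obs) == 0L) return(missing_matches)
  if (missing_matches) {
    length(unique(obs)) == 1L
  } else {
    length(obs) == length(a) && length(unique(obs)) == 1L
  }
}

## brute-force scan: for every SNP position, extend the interval while the
## slice stays identical; collapse duplicated intervals
oracle_scan <- function(hm, members, missing_matches = TRUE) {
  v <- hm$variants
  M <- nrow(v)
  ag <- vapply(seq_len(M), function(j)
    oracle_site_agrees(hm, members, j, missing_matches), logical(1))
  counted <- vapply(seq_len(M), function(j) {
    a <- hm$alleles[members, j]
    !anyNA(a) && length(unique(a)) == 1L
  }, logical(1))
  segs <- list()
  for (j in seq_len(M)) {
    if (!ag[j]) next
    a <- j
    while (a > 1L && v$chrom[a - 1L] == v$chrom[j] && ag[a - 1L]) a <- a - 1L
    b <- j
    while (b < M && v$chrom[b + 1L] == v$chrom[j] && ag[b + 1L]) b <- b + 1L
    segs[[length(segs) + 1L]] <- c(a, b)
  }
  if (!length(segs)) {
    return(data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0), n_snps = integer(0)))
  }
  segs <- unique(do.call(rbind, segs))
  out <- data.frame(chrom = v$chrom[segs[, 1]],
                    start_idx = segs[, 1], end_idx = segs[, 2],
                    n_snps = vapply(seq_len(nrow(segs)), function(r)
                      sum(counted[segs[r, 1]:segs[r, 2]]), integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[out$n_snps > 0L, , drop = FALSE]
  out[order(out$chrom, out$start_idx), , drop = FALSE]
}

## cohort with two carriers replaced by full siblings whose parents are
## generated alongside but EXCLUDED from the final matrix (the screen's
## control panel must not contain the latent pedigree)
make_sib_cohort <- function(n_controls, n_carriers, n_snps, chroms,
                            sibs = c("P01", "P02")) {
  cfg <- sim_config(n_controls = n_controls + 2L, n_carriers = n_carriers,
                    chrom_names = chroms, n_snps = n_snps, missing_rate = 0)
  hm <- simulate_background(cfg)
  par1 <- sprintf("C%03d", n_controls + 1L)
  par2 <- sprintf("C%03d", n_controls + 2L)
  al <- hm$alleles
  rows_of <- function(s) 2L * match(s, hm$samples) - c(1L, 0L)
  f <- rows_of(par1)
  m <- rows_of(par2)
  for (child in sibs) {
    cr <- rows_of(child)
    for (ch in unique(hm$variants$chrom)) {
      cols <- which(hm$variants$chrom == ch)
      al[cr[1], cols] <- al[sample(f, 1), cols]
      al[cr[2], cols] <- al[sample(m, 1), cols]
    }
  }
  keep <- setdiff(hm$samples, c(par1, par2))
  keep_rows <- c(rbind(2L * match(keep, hm$samples) - 1L,
                       2L * match(keep, hm$samples)))
  hm2 <- haplotype_matrix(al[keep_rows, , drop = FALSE], keep, hm$variants)
  sheet <- sim_sample_sheet(cfg)
  sheet <- sheet[sheet$sample %in% keep, ]
  rownames(sheet) <- NULL
  list(gm = as_genotype_matrix(hm2), sheet = sheet)
}

## genotype cohort drawn from per-site frequencies (no structure, no LD)
random_gm <- function(n, M, pmin = 0.1, pmax = 0.9) {
  p <- runif(M, pmin, pmax)
  make_gm(matrix(rbinom(n * M, 2L, rep(p, each = n)), n, M, byrow = FALSE))
}
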