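## planted-fixture builder: n_car carrier haplotypes identical over columns
## seg_lo..seg_hi around a focal column, engineered mismatches just outside
planted_fixture <- function(n_car = 5L, n_snps = 500L, seg_lo = 100L,
                            seg_hi = 399L, focal = 250L) {
  n_hap <- 2L * (n_car + 3L)                       # carriers + 3 controls
  al <- matrix(rbinom(n_hap * n_snps, 1L, 0.5), n_hap, n_snps)
  founder <- rbinom(n_snps, 1L, 0.5)
  founder[focal] <- 1L
  car_rows <- 2L * seq_len(n_car) - 1L             # phase 0 of each carrier
  for (r in car_rows) {
    al[r, seg_lo:seg_hi] <- founder[seg_lo:seg_hi]
    al[r, focal] <- 1L
    ## engineered mismatch immediately outside the planted segment
    al[r, seg_lo - 1L] <- if (r == car_rows[1]) 0L else 1L
    al[r, seg_hi + 1L] <- if (r == car_rows[1]) 0L else 1L
  }
  non_car <- setdiff(seq_len(n_hap), car_rows)
  al[non_car, focal] <- 0L
  hm <- make_hm(al, chrom = "21")
  spec <- focal_spec("21", hm$variants$pos_bp[focal],
                     carriers = paste0("S", seq_len(n_car)), risk_allele = 1L)
  list(hm = hm, spec = spec)
}

test_that("carrier haplotype selection follows the risk allele and tie rule", {
  set.seed(51)
  fx <- planted_fixture()
  rows <- carrier_haplotypes(fx$hm, fx$spec)
  expect_length(rows, 5L)
  expect_equal(unname(rows), 2L * 1:5 - 1L)        # risk is on phase 0
  expect_equal(names(rows), paste0("S", 1:5, "_0"))

  ## risk allele on phase 1 selects phase 1
  al2 <- fx$hm$alleles
  al2[1L, ] <- 0L                                   # S1 phase0 loses the allele
  al2[2L, ] <- fx$hm$alleles[1L, ]                  # ...it moves to phase 1
  hm2 <- haplotype_matrix(al2, fx$hm$samples, fx$hm$variants)
  rows2 <- carrier_haplotypes(hm2, fx$spec)
  expect_equal(unname(rows2[1]), 2L)

  ## homozygous carrier contributes phase 0
  al3 <- fx$hm$alleles
  al3[2L, ] <- al3[1L, ]
  hm3 <- haplotype_matrix(al3, fx$hm$samples, fx$hm$variants)
  expect_equal(unname(carrier_haplotypes(hm3, fx$spec)[1]), 1L)

  ## a carrier without the risk allele anywhere is an error naming it
  al4 <- fx$hm$alleles
  al4[1:2, ] <- 0L
  hm4 <- haplotype_matrix(al4, fx$hm$samples, fx$hm$variants)
  expect_error(carrier_haplotypes(hm4, fx$spec), "S1")
})

test_that("the planted 300-SNP segment is recovered exactly and maximally", {
  set.seed(52)
  fx <- planted_fixture()
  seg <- focal_shared_segment(fx$hm, fx$spec)
  expect_equal(seg$n_snps, 300L)
  expect_equal(seg$start_idx, 100L)
  expect_equal(seg$end_idx, 399L)
  expect_equal(seg$length_bp, seg$end_bp - seg$start_bp)
  ## maximality: a mismatch at the SNP adjacent to the focal truncates
  al <- fx$hm$alleles
  al[1L, 251L] <- 1L - al[1L, 251L]
  hm2 <- haplotype_matrix(al, fx$hm$samples, fx$hm$variants)
  seg2 <- focal_shared_segment(hm2, fx$spec)
  expect_equal(seg2$end_idx, 250L)
  expect_equal(seg2$start_idx, 100L)
})

test_that("scan yields one segment for identical members, two around a mismatch", {
  al <- matrix(0L, 4, 1000)
  hm <- make_hm(al)
  segs <- genomewide_segment_scan(hm, c(1L, 3L))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 1000L)

  al[1, 500] <- 1L
  hm <- make_hm(al)
  segs <- genomewide_segment_scan(hm, c(1L, 3L))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start_idx, c(1L, 501L))
  expect_equal(segs$end_idx, c(499L, 1000L))
  expect_error(genomewide_segment_scan(hm, 1L), "at least 2")
})

test_that("segment detection agrees with the brute-force oracle", {
  set.seed(53)
  for (rep in 1:20) {
    n_hap <- 2L * sample(2:6, 1)
    n_snps <- sample(c(80L, 150L, 300L), 1)
    miss <- sample(c(0, 0.05, 0.15), 1)
    hm <- random_hm(n_hap, n_snps, miss = miss, two_chrom = rep %% 2 == 0)
    k <- sample(2:min(5, n_hap), 1)
    members <- sample(n_hap, k)
    for (mm in c(TRUE, FALSE)) {
      got <- genomewide_segment_scan(hm, members, missing_matches = mm)
      want <- oracle_scan(hm, members, missing_matches = mm)
      got <- got[order(got$chrom, got$start_idx), ]
      expect_equal(got$start_idx, want$start_idx)
      expect_equal(got$end_idx, want$end_idx)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("every emitted segment is genuinely identical across its members", {
  set.seed(54)
  hm <- random_hm(8, 300, miss = 0.1)
  members <- c(1L, 4L, 6L)
  segs <- genomewide_segment_scan(hm, members)
  for (r in seq_len(nrow(segs))) {
    sl <- hm$alleles[members, segs$start_idx[r]:segs$end_idx[r], drop = FALSE]
    consensus <- apply(sl, 2, function(col) {
      obs <- unique(col[!is.na(col)])
      expect_lte(length(obs), 1L)
    })
  }
})

test_that("missing alleles bridge segments but do not count, unless strict", {
  al <- matrix(0L, 4, 9)
  al[1, 5] <- NA
  hm <- make_hm(al)
  seg <- genomewide_segment_scan(hm, c(1L, 3L))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 8L)            # the NA site does not count
  strict <- genomewide_segment_scan(hm, c(1L, 3L), missing_matches = FALSE)
  expect_equal(nrow(strict), 2L)          # the NA site breaks the run
  expect_equal(strict$n_snps, c(4L, 4L))
})

test_that("adding members never lengthens the focal segment", {
  set.seed(55)
  for (rep in 1:10) {
    cfg <- sim_config(n_controls = 6, n_carriers = 7, n_snps = 600,
                      chrom_names = "21", missing_rate = 0.02,
                      founder_tmrca = 30)
    co <- sim_cohort(cfg, seed = 100 + rep)
    members <- carrier_haplotypes(co$hm, co$spec)
    prev_snps <- Inf; prev_bp <- Inf
    for (k in 2:7) {
      seg <- focal_shared_segment(co$hm, co$spec, members = members[1:k])
      expect_lte(seg$n_snps, prev_snps)
      expect_lte(seg$length_bp, prev_bp)
      prev_snps <- seg$n_snps; prev_bp <- seg$length_bp
    }
  }
})

test_that("rank statistic follows its definition and counts itself", {
  mk_scan <- function(n_snps_vec) {
    M <- length(n_snps_vec)
    data.frame(chrom = "1", start_bp = seq_len(M) * 10L,
               end_bp = seq_len(M) * 10L + n_snps_vec,
               start_idx = seq_len(M) * 2L, end_idx = seq_len(M) * 2L + 1L,
               n_snps = n_snps_vec,
               length_bp = n_snps_vec,
               members = "x", stringsAsFactors = FALSE)
  }
  scan <- mk_scan(c(300L, rep(5L, 9999L)))
  focal <- scan[1, ]
  rk <- rank_statistics(focal, scan)
  expect_equal(rk$p[rk$metric == "snps"], 1 / 10000)
  expect_equal(rk$n_total, c(10000L, 10000L))

  ## two other segments at least as large -> p = 3/N
  scan2 <- mk_scan(c(47L, 47L, 51L, rep(5L, 97L)))
  rk2 <- rank_statistics(scan2[1, ], scan2)
  expect_equal(rk2$p[rk2$metric == "snps"], 3 / 100)
  expect_error(rank_statistics(scan2[1, ], scan2[0, ]), "empty")

  ## excluding a radius around the focal locus shrinks the null set
  rk3 <- rank_statistics(scan2[1, ], scan2, exclude_radius_bp = 1e6)
  expect_equal(rk3$n_total[1], 1L)
})

test_that("SNP-count rank p-values are conservative under exchangeable draws", {
  set.seed(56)
  ps <- replicate(120, {
    cfg <- sim_config(n_controls = 8, n_carriers = 5, n_snps = 400,
                      chrom_names = "1", missing_rate = 0)
    co <- sim_cohort(cfg, seed = sample.int(1e6, 1), plant = FALSE)
    rows <- 2L * match(paste0("P0", 1:5), co$hm$samples) -
      sample(c(0L, 1L), 5, TRUE)
    scan <- genomewide_segment_scan(co$hm, rows)
    focal <- scan[sample.int(nrow(scan), 1), ]
    rank_statistics(focal, scan)$p[1]
  })
  ## stochastically >= uniform: the empirical CDF never sits above x + noise
  for (x in c(0.1, 0.25, 0.5, 0.75)) {
    expect_lte(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / length(ps)))
  }
})

test_that("patient-control null counts planted tracts and bounds zero counts", {
  set.seed(57)
  fx <- planted_fixture(n_car = 3L, n_snps = 400L, seg_lo = 100L,
                        seg_hi = 299L, focal = 200L)
  ## plant a long tract shared between carrier S1's risk haplotype and
  ## control S4's first haplotype
  al <- fx$hm$alleles
  ctrl_row <- 2L * match("S4", fx$hm$samples) - 1L
  al[ctrl_row, 50:349] <- al[1L, 50:349]
  al[ctrl_row, fx$spec$pos_bp / 1000] <- 0L
  al[ctrl_row, 200L] <- 0L   # control never carries the risk allele
  hm <- haplotype_matrix(al, fx$hm$samples, fx$hm$variants)
  res <- patient_control_null(hm, fx$spec, controls = c("S4", "S5", "S6"),
                              target_snps = 150L, target_bp = 120000L,
                              alpha = 0.05)
  expect_equal(res$bonferroni, 0.05 / 9)
  expect_equal(res$n_tests, 9L)
  p1 <- res$per_patient[res$per_patient$sample == "S1", ]
  expect_gte(p1$n_ge_snps, 1L)            # the planted tract is counted
  ## an impossible target gives the one-sided zero bound
  res2 <- patient_control_null(hm, fx$spec, controls = c("S5", "S6"),
                               target_snps = 10000L, target_bp = 1e9)
  expect_true(all(res2$per_patient$zero_bound_snps))
  expect_equal(res2$per_patient$p_snps,
               1 / (res2$per_patient$n_total + 1))
  expect_true(all(res2$per_patient$p_snps > 0))
})

test_that("homozygous carriers can try both phases for the longer segment", {
  set.seed(58)
  fx <- planted_fixture()
  al <- fx$hm$alleles
  ## make S1 homozygous with a LONGER founder match on phase 1
  al[2L, ] <- al[1L, ]
  al[2L, 99L] <- al[3L, 99L]    # phase 1 extends one SNP further left
  al[1L, 99L] <- 1L - al[3L, 99L]
  hm <- haplotype_matrix(al, fx$hm$samples, fx$hm$variants)
  seg_default <- focal_shared_segment(hm, fx$spec)
  seg_both <- focal_shared_segment(hm, fx$spec, try_both_phases = TRUE)
  expect_gte(seg_both$n_snps, seg_default$n_snps)
})
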