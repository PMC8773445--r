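test_that("missingness filter removes by strict threshold, variants first", {
  calls <- matrix(1L, 10, 4)
  calls[1, 2] <- NA                  # variant 2: 10% missing -> removed
  gm <- make_gm(calls)
  res <- filter_missingness(gm, qc_thresholds())
  expect_equal(n_variants(res$gm), 3L)
  expect_false("1_2000" %in% res$gm$variants$id)
  expect_equal(res$report$removed_variants, 1L)

  ## fully observed matrix is untouched
  res2 <- filter_missingness(make_gm(matrix(1L, 5, 5)))
  expect_equal(dim(res2$gm$calls), c(5L, 5L))
  expect_equal(res2$report$removed_variants + res2$report$removed_samples, 0L)
})

test_that("missingness removal set equals a brute-force recount", {
  set.seed(31)
  calls <- matrix(sample(c(0:2, NA), 600, TRUE, prob = c(.3, .3, .3, .1)),
                  20, 30)
  gm <- make_gm(calls)
  thr <- qc_thresholds(max_variant_missing = 0.12, max_sample_missing = 0.2)
  res <- filter_missingness(gm, thr)
  keep_v <- vapply(seq_len(30), function(j) sum(is.na(calls[, j])) / 20 < 0.12,
                   logical(1))
  keep_s <- vapply(seq_len(20), function(i) {
    sum(is.na(calls[i, keep_v])) / sum(keep_v) < 0.2
  }, logical(1))
  expect_identical(res$gm$variants$id, gm$variants$id[keep_v])
  expect_identical(res$gm$samples, gm$samples[keep_s])
})

test_that("exact HWE test equals the enumeration oracle on assorted counts", {
  cases <- list(c(2, 4, 2), c(0, 4, 0), c(10, 1, 10), c(3, 7, 9),
                c(1, 0, 1), c(0, 1, 0), c(12, 0, 12), c(7, 12, 2))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  expect_equal(hwe_exact_test(5, 0, 0), 1)        # monomorphic convention
  expect_error(hwe_exact_test(-1, 0, 1), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("exact HWE test equals the oracle for every triple with total <= 20", {
  for (n in 1:20) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        cc <- n - a - b
        expect_equal(hwe_exact_test(a, b, cc), oracle_hwe(a, b, cc),
                     tolerance = 1e-10,
                     label = sprintf("triple (%d,%d,%d)", a, b, cc))
      }
    }
  }
})

test_that("HWE filter applies the realized Bonferroni threshold", {
  set.seed(32)
  n <- 60
  p <- runif(1000, .2, .8)
  calls <- matrix(rbinom(n * 1000, 2L, rep(p, each = n)), n, 1000)
  calls[, 1] <- 1L                   # all-heterozygote: extreme HWE violation
  gm <- make_gm(calls)
  res <- hwe_filter(gm, qc_thresholds(hwe_alpha = 0.05))
  expect_equal(res$report$realized_threshold, 0.05 / 1000)
  expect_false("1_1000" %in% res$gm$variants$id)   # planted variant removed
  ## under the null essentially nothing else is removed at 5e-5
  expect_lte(res$report$removed_variants, 2L)
})

test_that("MAF filter is strict at the boundary and matches a recount", {
  ## singleton alt among 100 samples: MAF 0.005 < 0.01 -> removed;
  ## one alt in 50 samples: MAF exactly 0.01 -> retained
  calls <- matrix(0L, 100, 3)
  calls[1, 1] <- 1L
  calls[1:50, 2] <- rep(c(1L, 0L), c(1, 49))
  calls[, 3] <- rep(c(0L, 1L, 2L), c(30, 40, 30))
  calls[51:100, 2] <- NA             # variant 2 observed in 50 samples only
  gm <- make_gm(calls)
  res <- maf_filter(gm, qc_thresholds(min_maf = 0.01))
  expect_identical(res$gm$variants$id, c("1_2000", "1_3000"))

  set.seed(33)
  calls <- matrix(rbinom(40 * 50, 2L, rep(runif(50, 0, 0.2), each = 40)),
                  40, 50)
  gm <- make_gm(calls)
  res <- maf_filter(gm, qc_thresholds(min_maf = 0.05))
  maf <- vapply(seq_len(50), function(j) {
    f <- mean(calls[, j]) / 2
    min(f, 1 - f)
  }, numeric(1))
  expect_identical(res$gm$variants$id, gm$variants$id[maf >= 0.05])
})

test_that("LD pruning removes duplicates and leaves independent variants", {
  set.seed(34)
  n <- 400
  g <- rbinom(n, 2L, 0.4)
  calls <- cbind(g, g, rbinom(n, 2L, 0.5))
  gm <- make_gm(calls)
  res <- ld_prune(gm, qc_thresholds(ld_window = 10, ld_step = 5, ld_r2 = 0.1))
  expect_equal(res$report$removed_variants, 1L)
  expect_true("1_1000" %in% res$kept_ids)    # later duplicate removed on tie

  calls <- matrix(rbinom(n * 30, 2L, rep(runif(30, .3, .7), each = n)), n, 30)
  gm <- make_gm(calls)
  res <- ld_prune(gm, qc_thresholds(ld_window = 10, ld_step = 5, ld_r2 = 0.5))
  expect_equal(res$report$removed_variants, 0L)
})

test_that("no surviving within-window pair exceeds the r2 threshold", {
  set.seed(35)
  cfg <- sim_config(n_controls = 40, n_carriers = 2, n_snps = 60,
                    chrom_names = "1", copy_prob = 0.85,
                    missing_rate = 0)
  gm <- as_genotype_matrix(simulate_background(cfg))
  thr <- qc_thresholds(ld_window = 15, ld_step = 5, ld_r2 = 0.2)
  res <- ld_prune(gm, thr)
  kept <- match(res$kept_ids, gm$variants$id)
  ## exhaustive post-hoc check over every window of the same definition
  start <- 1L
  repeat {
    stop_at <- min(start + thr$ld_window - 1L, n_variants(gm))
    win <- intersect(start:stop_at, kept)
    if (length(win) >= 2L) {
      cc <- suppressWarnings(
        stats::cor(gm$calls[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))
      diag(cc) <- 0
      expect_lte(max(cc^2, na.rm = TRUE), thr$ld_r2)
    }
    if (stop_at >= n_variants(gm)) break
    start <- start + thr$ld_step
  }
  expect_gt(length(kept), 0L)
  expect_lt(length(kept), 60L)       # the LD fixture must actually prune
})

test_that("the QC stack is an order-fixed pure function", {
  set.seed(36)
  cfg <- sim_config(n_controls = 30, n_carriers = 3, n_snps = 120,
                    chrom_names = "1", missing_rate = 0.03)
  gm <- as_genotype_matrix(sim_cohort(cfg, seed = 5)$hm)
  r1 <- run_qc(gm, qc_thresholds())
  r2 <- run_qc(gm, qc_thresholds())
  expect_identical(r1$report, r2$report)
  expect_identical(r1$gm$calls, r2$gm$calls)
  expect_equal(vapply(r1$report$steps, `[[`, "", "step"),
               c("missingness", "hwe", "maf", "ld_prune"))
  ## removal accounting is consistent
  expect_equal(r1$report$initial[["variants"]] -
                 sum(vapply(r1$report$steps, `[[`, 0L, "removed_variants")),
               r1$report$final[["variants"]])
})

test_that("HWE type-I rate under the null stays within binomial bounds", {
  set.seed(37)
  n <- 80
  M <- 1500
  p <- runif(M, 0.1, 0.9)
  calls <- matrix(rbinom(n * M, 2L, rep(p, each = n)), n, M)
  gm <- make_gm(calls)
  pv <- vapply(seq_len(M), function(j) {
    hwe_exact_test(sum(calls[, j] == 0L), sum(calls[, j] == 1L),
                   sum(calls[, j] == 2L))
  }, numeric(1))
  alpha <- 0.05
  expect_lte(mean(pv < alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / M))
})
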