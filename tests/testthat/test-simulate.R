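test_that("generation is byte-identical under a fixed (config, seed)", {
  cfg <- sim_config(n_controls = 10, n_carriers = 3, n_snps = 300,
                    missing_rate = 0.02)
  a <- sim_cohort(cfg, seed = 99)
  b <- sim_cohort(cfg, seed = 99)
  expect_identical(a$hm$alleles, b$hm$alleles)
  expect_identical(a$truth$carriers, b$truth$carriers)
  c <- sim_cohort(cfg, seed = 100)
  expect_false(identical(a$hm$alleles, c$hm$alleles))
})

test_that("copying probability controls adjacent-site correlation", {
  adj_r2 <- function(copy_prob, seed) {
    cfg <- sim_config(n_controls = 60, n_carriers = 2, n_snps = 300,
                      chrom_names = "1", copy_prob = copy_prob,
                      missing_rate = 0)
    hm <- simulate_background(cfg, seed = seed)
    al <- hm$alleles
    r2 <- vapply(seq_len(ncol(al) - 1L), function(j) {
      suppressWarnings(stats::cor(al[, j], al[, j + 1L])^2)
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  r0 <- adj_r2(0, 71)
  r97 <- adj_r2(0.97, 72)
  expect_lt(r0, 0.03)                     # ~1/n_hap chance correlation
  expect_gt(r97, 0.1)
  expect_gt(r97, 10 * r0)
  ## near-1 copying also yields long perfectly shared haplotype runs
  cfg <- sim_config(n_controls = 20, n_carriers = 2, n_snps = 300,
                    chrom_names = "1", copy_prob = 0.97, missing_rate = 0)
  hm <- simulate_background(cfg, seed = 72)
  longest <- max(vapply(seq(2, 40, by = 2), function(r) {
    max(genomewide_segment_scan(hm, c(r - 1L, r))$n_snps)
  }, numeric(1)))
  expect_gt(longest, 50)
})

test_that("the founder event is planted correctly", {
  cfg <- sim_config(n_controls = 30, n_carriers = 6, n_snps = 1000,
                    missing_rate = 0, founder_tmrca = 40)
  co <- sim_cohort(cfg, seed = 73)
  j <- match(paste0(cfg$focal_chrom, "_snp00500"), co$hm$variants$id)
  focal_alleles <- co$hm$alleles[, j]
  sheet <- co$sheet
  ctrl_rows <- which(rep(sheet$role, each = 2) == "control")
  expect_true(all(focal_alleles[ctrl_rows] == 0L))   # controls never carry it
  ## every carrier carries it on exactly the recorded phase
  for (r in seq_len(nrow(co$truth$carriers))) {
    tr <- co$truth$carriers[r, ]
    row <- 2L * match(tr$sample, co$hm$samples) - 1L + tr$phase
    expect_equal(co$hm$alleles[row, j], 1L)
    ## the retained interval contains the focal position
    expect_lte(tr$start_bp, co$truth$focal_pos)
    expect_gte(tr$end_bp, co$truth$focal_pos)
  }
  ## heterozygous by default: the other phase is reference at the focal site
  others <- 2L * match(co$truth$carriers$sample, co$hm$samples) - 1L +
    (1L - co$truth$carriers$phase)
  expect_true(all(co$hm$alleles[others, j] == 0L))

  ## homozygous flag plants both phases
  cfg2 <- sim_config(n_controls = 10, n_carriers = 3, n_snps = 400,
                     missing_rate = 0, homozygous_carriers = TRUE)
  co2 <- sim_cohort(cfg2, seed = 74)
  j2 <- match(paste0(cfg2$focal_chrom, "_snp00200"), co2$hm$variants$id)
  car_rows <- which(rep(co2$sheet$role, each = 2) == "carrier")
  expect_true(all(co2$hm$alleles[car_rows, j2] == 1L))
  expect_equal(nrow(co2$truth$carriers), 6L)
})

test_that("near-zero erosion retains almost the whole chromosome", {
  cfg <- sim_config(n_controls = 5, n_carriers = 4, n_snps = 500,
                    missing_rate = 0, founder_tmrca = 0.1)
  co <- sim_cohort(cfg, seed = 75)
  chrom_pos <- co$hm$variants$pos_bp[co$hm$variants$chrom == cfg$focal_chrom]
  span <- diff(range(chrom_pos))
  retained <- co$truth$carriers$end_bp - co$truth$carriers$start_bp
  expect_true(all(retained > 0.9 * span))
})

test_that("erosion matches the exponential mean at the configured rate", {
  ## many carriers, one replicate: mean one-sided genetic length ~ 1/t*
  t_star <- 50
  cfg <- sim_config(n_controls = 2, n_carriers = 150, n_snps = 2000,
                    chrom_names = "1", missing_rate = 0,
                    founder_tmrca = t_star, map_rate_cm_mb = 1)
  co <- sim_cohort(cfg, seed = 76)
  tr <- co$truth$carriers
  left_m <- (co$truth$focal_pos - tr$start_bp) / 1e6 / 100   # Morgans
  right_m <- (tr$end_bp - co$truth$focal_pos) / 1e6 / 100
  sides <- c(left_m, right_m)
  se <- sd(sides) / sqrt(length(sides))
  expect_lt(abs(mean(sides) - 1 / t_star), 4 * se + 0.002)
})

test_that("missingness injection hits its rate and respects protection", {
  cfg <- sim_config(n_controls = 25, n_carriers = 2, n_snps = 200,
                    missing_rate = 0)
  hm <- simulate_background(cfg, seed = 77)
  expect_identical(inject_missingness(hm, 0)$alleles, hm$alleles)
  masked <- inject_missingness(hm, 0.5, seed = 78, protect_variants = 1:5)
  n_cells <- length(masked$alleles) - nrow(masked$alleles) * 5L
  rate <- sum(is.na(masked$alleles)) / n_cells
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n_cells))
  expect_true(all(!is.na(masked$alleles[, 1:5])))
  expect_identical(inject_missingness(hm, 0.5, seed = 78)$alleles,
                   inject_missingness(hm, 0.5, seed = 78)$alleles)
})

test_that("a written cohort round-trips through the package readers", {
  cfg <- sim_config(n_controls = 8, n_carriers = 3, n_snps = 150,
                    missing_rate = 0.02)
  co <- sim_cohort(cfg, seed = 79)
  out <- withr::local_tempdir()
  paths <- write_cohort(co, out)
  expect_true(all(file.exists(paths)))
  back <- read_phased_vcf(paths[["vcf"]])
  expect_identical(unname(back$hap$alleles), unname(co$hm$alleles))
  expect_identical(back$hap$samples, co$hm$samples)
  sheet <- read_sample_sheet(paths[["sheet"]])
  expect_identical(sheet, co$sheet)
  expect_setequal(sheet$role, c("carrier", "control"))
  map <- read_genetic_map(paths[["map"]])
  expect_equal(genetic_length(map, cfg$focal_chrom,
                              co$truth$focal_pos, co$truth$focal_pos + 1e6),
               0.01, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_true(all(truth$carriers$start_bp <= truth$focal_pos &
                    truth$carriers$end_bp >= truth$focal_pos))
})

test_that("the detected focal segment contains the planted intersection", {
  set.seed(80)
  for (rep in 1:10) {
    cfg <- sim_config(n_controls = 10, n_carriers = 5, n_snps = 1000,
                      missing_rate = 0, founder_tmrca = 40)
    co <- sim_cohort(cfg, seed = 200 + rep)
    seg <- focal_shared_segment(co$hm, co$spec)
    tr <- co$truth$carriers
    expect_lte(seg$start_bp, max(tr$start_bp))
    expect_gte(seg$end_bp, min(tr$end_bp))
    expect_gte(seg$n_snps, 1L)
  }
})
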