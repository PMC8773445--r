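#!/usr/bin/env Rscript

## Stage 2 — quality control.
##
## Applies the array QC stack to the simulated cohort: per-variant and
## per-sample missingness (< 0.05), exact Hardy-Weinberg test with
## Bonferroni correction (family-wise alpha 0.05), MAF >= 0.01, and
## sliding-window LD pruning (50 SNPs, step 5, r2 0.1) for the
## structure-analysis marker set.

suppressPackageStartupMessages(library(founderhap))

io <- read_phased_vcf("results/analysis/cohort/cohort.vcf")
gm <- io$gen

thr <- qc_thresholds()
post_qc <- run_qc(gm, thr, prune = FALSE)
pruned <- ld_prune(post_qc$gm, thr)

dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
write_qc_report(post_qc$report, "results/analysis/qc_report.json")
writeLines(pruned$kept_ids, "results/analysis/pruned_variants.txt")

print(post_qc$report)
cat(sprintf("LD pruning: %d of %d post-QC variants retained (threshold r2 = %g)\n",
            length(pruned$kept_ids), n_variants(post_qc$gm), thr$ld_r2))
cat(sprintf("realized HWE threshold: %.3g (alpha %.2f / %d variants)\n",
            post_qc$report$steps[[2]]$realized_threshold,
            thr$hwe_alpha, post_qc$report$steps[[2]]$n_tested))
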