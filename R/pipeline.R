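## End-to-end orchestration: simulate (or load) -> qc -> structure ->
## share -> tmrca, collected into a machine-readable run report. Stages are
## pure functions of prior-stage outputs; identical (config, seed) gives an
## identical report.

.known_keys <- list(
  top = c("seed", "stages", "sim", "qc", "tmrca", "share", "out_dir",
          "inputs"),
  stages = c("qc", "structure", "share", "tmrca"),
  share = c("exclude_radius_bp", "missing_matches", "alpha"),
  tmrca = c("convention", "c", "t_max", "grid_step", "generation_years",
            "prior", "prior_rate"),
  inputs = c("vcf", "sheet", "map", "focal_chrom", "focal_pos",
             "risk_allele"))

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown ", where, " config key(s): ", paste(unknown, collapse = ", "))
  }
}

#' Read and validate a pipeline run configuration
#'
#' A single YAML document with blocks `seed`, `stages` (logical toggles),
#' `sim` (arguments of [sim_config()]), `qc` (arguments of
#' [qc_thresholds()]), `share`, `tmrca` (arguments of [tmrca_model()]) and
#' optionally `inputs` (paths to a phased VCF, sample sheet and genetic map
#' plus the focal variant, to run on real data instead of a simulated
#' cohort). Unknown keys are errors.
#'
#' @param path Path to the YAML file.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list built in code.
#' @export
validate_run_config <- function(cfg) {
  .check_keys(cfg, .known_keys$top, "top-level")
  if (!is.null(cfg$stages)) .check_keys(cfg$stages, .known_keys$stages, "stages")
  if (!is.null(cfg$sim)) .check_keys(cfg$sim, names(formals(sim_config)), "sim")
  if (!is.null(cfg$qc)) .check_keys(cfg$qc, names(formals(qc_thresholds)), "qc")
  if (!is.null(cfg$share)) .check_keys(cfg$share, .known_keys$share, "share")
  if (!is.null(cfg$tmrca)) .check_keys(cfg$tmrca, .known_keys$tmrca, "tmrca")
  if (!is.null(cfg$inputs)) {
    .check_keys(cfg$inputs, .known_keys$inputs, "inputs")
    for (f in intersect(c("vcf", "sheet", "map"), names(cfg$inputs))) {
      if (!file.exists(cfg$inputs[[f]])) {
        stop("configured input does not exist: ", cfg$inputs[[f]])
      }
    }
  }
  cfg
}

.stage_on <- function(cfg, name) {
  is.null(cfg$stages[[name]]) || isTRUE(cfg$stages[[name]])
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a simulated cohort (default) or
#' on configured input files. A stage failure halts the run with an error
#' naming the stage; the partial report assembled so far is attached to the
#' error condition (`attr(cond, "report")`) and written to
#' `out_dir/report.json` when an output directory is configured.
#'
#' @param cfg Config list (see [read_run_config()]); built in code or from
#'   YAML.
#' @return An object of class `run_report` with one block per executed
#'   stage, the configuration echo and the seed.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- validate_run_config(cfg)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  report <- list(package_version = as.character(utils::packageVersion("founderhap")),
                 seed = seed, config = cfg)
  fail <- function(stage, e) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_run_report(structure(report, class = "run_report"),
                       file.path(cfg$out_dir, "report.json"))
    }
    cond <- simpleError(paste0("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e)))
    attr(cond, "report") <- structure(report, class = "run_report")
    stop(cond)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  ## --- data stage: simulate or load ---------------------------------------
  dat <- run_stage("data", {
    if (!is.null(cfg$inputs)) {
      io <- read_phased_vcf(cfg$inputs$vcf)
      sheet <- read_sample_sheet(cfg$inputs$sheet)
      map <- read_genetic_map(cfg$inputs$map)
      spec <- focal_spec(cfg$inputs$focal_chrom, cfg$inputs$focal_pos,
                         carriers = sheet$sample[sheet$role == "carrier"],
                         risk_allele = if (is.null(cfg$inputs$risk_allele)) 1L
                                       else cfg$inputs$risk_allele)
      list(hm = io$hap, sheet = sheet, map = map, spec = spec, truth = NULL)
    } else {
      sc <- do.call(sim_config, if (is.null(cfg$sim)) list() else cfg$sim)
      cohort <- sim_cohort(sc, seed = seed)
      list(hm = cohort$hm, sheet = cohort$sheet,
           map = constant_rate_map(sc$map_rate_cm_mb),
           spec = cohort$spec, truth = cohort$truth)
    }
  })
  gm <- as_genotype_matrix(dat$hm)
  report$data <- list(n_samples = n_samples(gm), n_variants = n_variants(gm),
                      n_carriers = sum(dat$sheet$role == "carrier"),
                      simulated = is.null(cfg$inputs))
  if (!is.null(dat$truth)) report$data$true_tmrca <- dat$truth$t_star

  ## --- qc ------------------------------------------------------------------
  gm_qc <- gm
  gm_pruned <- gm
  if (.stage_on(cfg, "qc")) {
    qc_res <- run_stage("qc", {
      thr <- do.call(qc_thresholds, if (is.null(cfg$qc)) list() else cfg$qc)
      unpruned <- run_qc(gm, thr, prune = FALSE)
      pruned <- ld_prune(unpruned$gm, thr)
      list(thr = thr, unpruned = unpruned, pruned = pruned)
    })
    gm_qc <- qc_res$unpruned$gm
    gm_pruned <- qc_res$pruned$gm
    report$qc <- list(report = unclass(qc_res$unpruned$report),
                      n_pruned = n_variants(gm_pruned))
  }

  ## --- structure -----------------------------------------------------------
  if (.stage_on(cfg, "structure")) {
    st <- run_stage("structure", {
      k <- min(10L, n_samples(gm_pruned) - 1L)
      pca <- run_pca(gm_pruned, k = k)
      screen <- relatedness_screen(gm_qc, dat$sheet)
      list(pca = pca, screen = screen)
    })
    report$structure <- list(
      pca_explained = st$pca$explained[seq_len(ncol(st$pca$scores))],
      relatedness = st$screen$verdicts,
      relatedness_threshold = st$screen$threshold,
      n_flagged = sum(st$screen$verdicts$flagged))
  }

  ## --- share ---------------------------------------------------------------
  seg <- NULL
  if (.stage_on(cfg, "share")) {
    sh <- run_stage("share", {
      mm <- if (is.null(cfg$share$missing_matches)) TRUE else
        cfg$share$missing_matches
      members <- carrier_haplotypes(dat$hm, dat$spec)
      focal <- focal_shared_segment(dat$hm, dat$spec, members = members,
                                    missing_matches = mm)
      scan <- genomewide_segment_scan(dat$hm, members, missing_matches = mm)
      ranks <- rank_statistics(
        focal, scan,
        exclude_radius_bp = if (is.null(cfg$share$exclude_radius_bp)) 0
                            else cfg$share$exclude_radius_bp)
      controls <- dat$sheet$sample[dat$sheet$role == "control"]
      ctrl_null <- patient_control_null(
        dat$hm, dat$spec, controls,
        target_snps = focal$n_snps, target_bp = focal$length_bp,
        alpha = if (is.null(cfg$share$alpha)) 0.05 else cfg$share$alpha,
        missing_matches = mm)
      pairwise <- pairwise_focal_segments(dat$hm, dat$spec,
                                          missing_matches = mm)
      list(focal = focal, ranks = ranks, ctrl_null = ctrl_null,
           pairwise = pairwise)
    })
    seg <- sh$focal
    report$share <- list(focal_segment = sh$focal, rank = sh$ranks,
                         control_null = unclass(sh$ctrl_null),
                         pairwise = sh$pairwise)
  }

  ## --- tmrca ---------------------------------------------------------------
  if (.stage_on(cfg, "tmrca") && !is.null(seg)) {
    tm <- run_stage("tmrca", {
      model <- do.call(tmrca_model,
                       if (is.null(cfg$tmrca)) list() else cfg$tmrca)
      n_car <- sum(dat$sheet$role == "carrier")
      post <- tmrca_from_segment(seg, dat$map, n_car, model)
      post
    })
    report$tmrca <- list(
      mean = tm$mean, mode = tm$mode, ci = as.list(tm$ci),
      ci_level = tm$ci_level, mean_years = tm$mean_years,
      length_morgans = tm$length_morgans, c = tm$c,
      generation_years = tm$model$generation_years,
      moment_estimate = tmrca_moment_estimate(tm$length_morgans, tm$c),
      posterior = tm)
  }

  report <- structure(report, class = "run_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_report(report, file.path(cfg$out_dir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("founderhap run report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  data:  %d samples x %d variants (%d carriers)%s\n",
              x$data$n_samples, x$data$n_variants, x$data$n_carriers,
              if (isTRUE(x$data$simulated)) " [simulated]" else ""))
  if (!is.null(x$qc)) {
    cat(sprintf("  qc:    %d variants post-QC, %d after LD pruning\n",
                x$qc$report$final[["variants"]], x$qc$n_pruned))
  }
  if (!is.null(x$structure)) {
    cat(sprintf("  structure: PC1 %.1f%% variance; %d relatedness flag(s)\n",
                100 * x$structure$pca_explained[1], x$structure$n_flagged))
  }
  if (!is.null(x$share)) {
    f <- x$share$focal_segment
    cat(sprintf("  share: focal segment %s:%d-%d (%d SNPs, %d bp); rank p (snps) = %.3g\n",
                f$chrom, f$start_bp, f$end_bp, f$n_snps, f$length_bp,
                x$share$rank$p[x$share$rank$metric == "snps"]))
  }
  if (!is.null(x$tmrca)) {
    cat(sprintf("  tmrca: mean %.1f generations (mode %.1f), ~%.0f years\n",
                x$tmrca$mean, x$tmrca$mode, x$tmrca$mean_years))
  } else {
    cat("  tmrca: not computed\n")
  }
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' The posterior grid is summarised (mean/mode/CI), not dumped.
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$tmrca)) out$tmrca$posterior <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Render a run report for human consumption
#'
#' Writes a text summary, the carrier-pair sharing matrix (SNP counts of
#' the pairwise focal segments) and, when present, the tMRCA posterior
#' curve as TSV; optionally a PNG of the posterior.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory.
#' @param png Also write a posterior-curve PNG.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, out_dir, png = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p_sum <- file.path(out_dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), p_sum)
  paths <- c(paths, p_sum)
  if (!is.null(report$share)) {
    pw <- report$share$pairwise
    carriers <- sort(unique(c(pw$sample1, pw$sample2)))
    m <- matrix(NA_integer_, length(carriers), length(carriers),
                dimnames = list(carriers, carriers))
    for (r in seq_len(nrow(pw))) {
      m[pw$sample1[r], pw$sample2[r]] <- pw$n_snps[r]
      m[pw$sample2[r], pw$sample1[r]] <- pw$n_snps[r]
    }
    p_mat <- file.path(out_dir, "sharing_matrix.tsv")
    utils::write.table(m, p_mat, sep = "\t", quote = FALSE, col.names = NA)
    paths <- c(paths, p_mat)
  }
  if (!is.null(report$tmrca)) {
    p_curve <- file.path(out_dir, "tmrca_posterior.tsv")
    write_tmrca_curve(report$tmrca$posterior, p_curve)
    paths <- c(paths, p_curve)
    if (png) {
      p_png <- file.path(out_dir, "tmrca_posterior.png")
      grDevices::png(p_png, width = 800, height = 500)
      g <- report$tmrca$posterior$grid
      keep <- g$density > max(g$density) / 1e4
      plot(g$t[keep], g$density[keep], type = "l", xlab = "generations",
           ylab = "posterior density", main = "tMRCA posterior")
      abline(v = report$tmrca$mean, lty = 2)
      grDevices::dev.off()
      paths <- c(paths, p_png)
    }
  } else {
    cat("tMRCA block absent; posterior outputs omitted\n",
        file = file.path(out_dir, "summary.txt"), append = TRUE)
  }
  invisible(paths)
}
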