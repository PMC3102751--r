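# End-to-end orchestration: simulate (optional) -> QC -> probesets ->
# covariate/SVA adjustment -> per-panel cis scans -> cross-panel replication
# -> headline report. Any panel can serve as the discovery cohort; all
# thresholds live in the config and are echoed into the report.

#' Pipeline configuration
#'
#' All analysis thresholds in one place; defaults are the study framework's
#' stated values (250 kb cis window, MAF 1%, replication p < 0.05, FDR 5%,
#' BF threshold 5, 100 matched resamples, age tolerance 3 years, reporter
#' alpha 0.001).
#'
#' @param simulation a [simulation_config()] (used when `simulate = TRUE`).
#' @param simulate generate synthetic panels (otherwise `panels` must be
#'   supplied to [run_pipeline()]).
#' @param discovery index of the discovery panel.
#' @param cis_window,maf_min,p_thresh,fdr,bf_threshold,bf_grid analysis
#'   thresholds.
#' @param use_sva adjust for surrogate variables.
#' @param compare_sva also run the scans without surrogate variables and
#'   report both (confounder-benefit comparison mode).
#' @param resample_sets,resample_age_tol matched-resampling design
#'   (`resample_sets = 0` disables the baseline).
#' @param priors a [bf_prior_spec()].
#' @param seed integer seed.
#'
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            simulate = TRUE, discovery = 1L,
                            cis_window = 250000, maf_min = 0.01,
                            p_thresh = 0.05, fdr = 0.05, bf_threshold = 5,
                            bf_grid = seq(0, 15, by = 1), use_sva = TRUE,
                            compare_sva = FALSE, resample_sets = 0,
                            resample_age_tol = 3, priors = bf_prior_spec(),
                            seed = 1L) {
  structure(list(simulation = simulation, simulate = simulate,
                 discovery = as.integer(discovery), cis_window = cis_window,
                 maf_min = maf_min, p_thresh = p_thresh, fdr = fdr,
                 bf_threshold = bf_threshold, bf_grid = bf_grid,
                 use_sva = use_sva, compare_sva = compare_sva,
                 resample_sets = resample_sets,
                 resample_age_tol = resample_age_tol, priors = priors,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; a
#' `simulation:` block overrides [simulation_config()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  sim <- do.call(simulation_config, raw$simulation %||% list())
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

# Prepare one panel: probeset construction, covariate/SVA adjustment, and a
# gene-level residual matrix (probesets of a gene averaged) so that traits
# join across platforms by gene id.
prepare_panel <- function(panel, use_sva, sva_seed) {
  ps <- cluster_probes_to_probesets(average_replicates(panel$expression))
  adj <- adjust_panel(panel, expr = ps$expr, use_sva = use_sva,
                      sva_args = list(seed = sva_seed))
  meta <- ps$expr$probe_meta
  genes <- unique(meta$gene_id)
  Y <- matrix(0, length(genes), ncol(adj$residuals),
              dimnames = list(genes, colnames(adj$residuals)))
  probe_snp <- stats::setNames(integer(length(genes)), genes)
  for (g in genes) {
    idx <- which(meta$gene_id == g)
    Y[g, ] <- colMeans(adj$residuals[idx, , drop = FALSE])
    probe_snp[g] <- sum(meta$n_probe_snps[idx])
  }
  list(probesets = ps, adjusted = adj, gene_residuals = Y,
       gene_probe_snp = probe_snp)
}

run_replication_arm <- function(prepared, panels, genes, config) {
  k_d <- config$discovery
  reps <- setdiff(seq_along(panels), k_d)
  scan_d <- cis_scan(prepared[[k_d]]$gene_residuals, panels[[k_d]]$genotypes,
                     genes, window = config$cis_window,
                     maf_min = config$maf_min, priors = config$priors)
  disc <- scan_d$best
  disc$probe_snp <- prepared[[k_d]]$gene_probe_snp[disc$gene_id]
  rep_stats <- lapply(reps, function(k)
    pair_association(disc, prepared[[k]]$gene_residuals,
                     panels[[k]]$genotypes, priors = config$priors))
  names(rep_stats) <- vapply(panels[reps], `[[`, "", "name")
  records <- assess_replication(disc, rep_stats, p_thresh = config$p_thresh)
  list(scan = scan_d, records = records)
}

#' Run the full discovery-and-replication pipeline
#'
#' Executes (optionally) simulation, probeset construction, covariate and
#' surrogate-variable adjustment, the cis scan on the discovery panel,
#' fixed-pair replication statistics on the remaining panels, the
#' replication assessment and rate curves, and (optionally) the matched
#' resampling baseline and an SVA-off comparison arm.
#'
#' @param config a [pipeline_config()].
#' @param panels optional list of [study_panel()] objects (required when
#'   `config$simulate` is `FALSE`).
#' @param outdir optional directory; when given, the report (JSON), records
#'   and curves (TSV) and the run manifest are written there.
#'
#' @return list of class `pipeline_result`: `records`, `curves`, `scan`,
#'   `baseline` (or NULL), `sva_off` comparison arm (or NULL), `report`
#'   (headline numbers), `manifest`, `truth` (when simulated).
#' @export
run_pipeline <- function(config, panels = NULL, outdir = NULL) {
  t0 <- Sys.time()
  truth <- NULL
  if (config$simulate) {
    sim <- simulate_multi_study(config$simulation)
    panels <- sim$panels
    truth <- sim$truth
  }
  assert_that(!is.null(panels) && length(panels) >= 1, "no input panels")
  single_panel <- length(panels) < 2
  if (single_panel)
    message("single panel supplied; replication stages skipped")
  seeds <- with_seed(config$seed, sample.int(2^31 - 1, length(panels) + 1))
  genes <- if (!is.null(truth))
    truth$genes[, c("gene_id", "chrom", "tss", "strand")]
  else {
    pm <- panels[[1]]$expression$probe_meta
    agg <- pm[!duplicated(pm$gene_id) & !is.na(pm$gene_id), ]
    data.frame(gene_id = agg$gene_id, chrom = agg$chrom,
               tss = ifelse(agg$strand == "-", agg$end, agg$start + 1L),
               strand = agg$strand, stringsAsFactors = FALSE)
  }
  prepared <- lapply(seq_along(panels), function(k)
    prepare_panel(panels[[k]], config$use_sva, seeds[k]))
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 n_panels = length(panels),
                 panel_sizes = vapply(panels, function(p)
                   length(p$genotypes$sample_ids), 1L),
                 discovery = config$discovery)
  result <- list(truth = truth, config = config)
  if (!single_panel) {
    arm <- run_replication_arm(prepared, panels, genes, config)
    curves <- replication_rate_curve(arm$records, config$bf_grid)
    elig <- arm$records$tested_all & !arm$records$indeterminate &
      !is.na(arm$records$log10_bf)
    sig <- elig & arm$records$log10_bf > config$bf_threshold
    report$n_genes_scanned <- nrow(arm$records)
    report$n_bf_over_threshold <- sum(sig)
    report$replication_rate_either <- mean(arm$records$replicated_either[sig])
    report$replication_rate_both <- mean(arm$records$replicated_both[sig])
    for (nm in attr(arm$records, "panel_names"))
      report[[paste0("replication_rate_", nm)]] <-
        mean(arm$records[[paste0("replicated_", nm)]][sig])
    result$scan <- arm$scan
    result$records <- arm$records
    result$curves <- curves
    if (config$compare_sva) {
      prep_off <- lapply(seq_along(panels), function(k)
        prepare_panel(panels[[k]], FALSE, seeds[k]))
      arm_off <- run_replication_arm(prep_off, panels, genes, config)
      sig_off <- arm_off$records$tested_all & !arm_off$records$indeterminate &
        !is.na(arm_off$records$log10_bf) &
        arm_off$records$log10_bf > config$bf_threshold
      report$n_bf_over_threshold_sva_off <- sum(sig_off)
      report$replication_rate_either_sva_off <-
        mean(arm_off$records$replicated_either[sig_off])
      result$sva_off <- arm_off
    }
    if (config$resample_sets > 0) {
      k_d <- config$discovery
      smallest <- which.min(report$panel_sizes[-k_d])
      target <- panels[-k_d][[smallest]]$demographics
      src <- panels[[k_d]]$demographics
      elig <- lapply(seq_len(nrow(target)), function(i)
        src$sample_id[src$sex == target$sex[i] &
                        src$population == target$population[i] &
                        abs(src$age - target$age[i]) <=
                          config$resample_age_tol])
      feasible <- !is.na(bipartite_match(elig))
      if (!all(feasible)) {
        message(sprintf("resampling: dropping %d unmatchable target rows",
                        sum(!feasible)))
        target <- target[feasible, , drop = FALSE]
      }
      sets <- matched_resample(panels[[k_d]], target,
                               n_sets = config$resample_sets,
                               age_tol = config$resample_age_tol,
                               seed = seeds[length(panels) + 1])
      disc <- result$scan$best
      disc <- disc[!is.na(disc$log10_bf), , drop = FALSE]
      result$baseline <- resampling_baseline(
        prepared[[k_d]]$gene_residuals, panels[[k_d]]$genotypes, disc, sets,
        p_thresh = config$p_thresh)
      bc <- baseline_rate_curve(result$baseline,
                                bf_grid = c(0, config$bf_threshold))
      report$baseline_rate_bf_over_threshold <-
        bc$sim_rate[bc$threshold == config$bf_threshold]
    }
  } else {
    scan1 <- cis_scan(prepared[[1]]$gene_residuals, panels[[1]]$genotypes,
                      genes,
                      window = config$cis_window, maf_min = config$maf_min,
                      priors = config$priors)
    result$scan <- scan1
    report$n_genes_scanned <- nrow(scan1$best)
    report$n_bf_over_threshold <- sum(scan1$best$log10_bf > config$bf_threshold,
                                      na.rm = TRUE)
  }
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  result$report <- report
  result$manifest <- list(config_hash = report$config_hash,
                          seed = config$seed,
                          package_version =
                            as.character(utils::packageVersion("eqtlrep")),
                          n_records = NROW(result$records),
                          timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  class(result) <- "pipeline_result"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(result$records))
      utils::write.table(as.data.frame(result$records),
                         file.path(outdir, "records.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(result$curves))
      utils::write.table(result$curves, file.path(outdir, "curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  panels: %s (discovery: panel %d)\n",
              paste(r$panel_sizes, collapse = "/"), r$discovery))
  if (!is.null(r$n_bf_over_threshold))
    cat(sprintf("  genes with log10 BF > %g: %d of %d\n",
                x$config$bf_threshold, r$n_bf_over_threshold,
                r$n_genes_scanned))
  if (!is.null(r$replication_rate_either))
    cat(sprintf("  replication (either/both): %.1f%% / %.1f%%\n",
                100 * r$replication_rate_either,
                100 * r$replication_rate_both))
  invisible(x)
}
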