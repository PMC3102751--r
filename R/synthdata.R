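# Multi-study synthetic data generator.
#
# Emulates the statistical structure of a three-cohort liver eQTL study:
# unequal panel sizes, shared cis/trans genetic effects, panel-specific hidden
# confounders, age/sex effects (sex genes enriched on chrX), a minority
# non-European population, technical replicates, platform-specific probe maps
# and probe-SNP hybridization artifacts. Every draw is a pure function of the
# seed, and per-gene variance fractions are book-kept exactly so parameter
# recovery can be asserted downstream.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the multi-study generator.
#' Defaults mirror the demographic structure of the emulated three-cohort
#' design (panel sizes 206/60/266, ~64/53/52% male, 11/8/0% non-European,
#' 2 technical replicates in the first two panels) and field-typical values
#' where the emulated study reports none.
#'
#' @param n_panels number of cohorts (>= 1; >= 2 for replication analyses).
#' @param panel_sizes samples per panel.
#' @param n_genes number of gene models.
#' @param n_snps_per_gene SNPs simulated in each gene's cis window.
#' @param cis_window cis definition, bp from the TSS (default 250 kb).
#' @param maf_range minor-allele-frequency range, each in (0, 0.5].
#' @param frac_cis_genes fraction of genes with a true cis effect.
#' @param cis_h2_range per-gene cis variance fraction range.
#' @param n_trans_regulators number of trans-acting SNPs.
#' @param trans_targets_per_regulator genes affected by each regulator.
#' @param trans_h2 variance fraction of a trans effect.
#' @param age_effect_sd,sex_effect_sd SD of planted age (per year) and sex
#'   (male minus female) effects, log2 units.
#' @param frac_age_genes,frac_sex_genes fractions of genes with such effects.
#' @param n_confounders_per_panel hidden confounders per panel.
#' @param confounder_var_frac variance fraction absorbed by confounders on
#'   loaded genes.
#' @param frac_confounded_genes fraction of genes loaded by each confounder.
#' @param frac_probe_snp per-panel fraction of probes overlapping a variant
#'   (defaults 0.274/0.191 for the first two platforms, then 0.274).
#' @param probe_artifact_delta log2 intensity decrease per artifact allele.
#' @param ld_decay adjacent-SNP haplotype copying probability in [0, 1).
#' @param frac_imputed fraction of SNPs reported as fractional dosages.
#' @param noise_sd per-measurement residual SD, log2 units.
#' @param n_replicates technical replicates per sample, recycled per panel.
#' @param n_probes_per_gene probes per gene on each platform.
#' @param male_frac,noneuro_frac per-panel design fractions.
#' @param age_range years, ages drawn uniformly.
#' @param seed integer seed that fully determines all output.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_panels = 3,
                              panel_sizes = c(206, 60, 266),
                              n_genes = 100,
                              n_snps_per_gene = 10,
                              cis_window = 250000,
                              maf_range = c(0.05, 0.5),
                              frac_cis_genes = 0.5,
                              cis_h2_range = c(0.05, 0.30),
                              n_trans_regulators = 2,
                              trans_targets_per_regulator = 3,
                              trans_h2 = 0.15,
                              age_effect_sd = 0.008,
                              sex_effect_sd = 0.4,
                              frac_age_genes = 0.3,
                              frac_sex_genes = 0.15,
                              n_confounders_per_panel = 5,
                              confounder_var_frac = 0.4,
                              frac_confounded_genes = 0.8,
                              frac_probe_snp = c(0.274, 0.191, 0.274),
                              probe_artifact_delta = 0.6,
                              ld_decay = 0.9,
                              frac_imputed = 0.3,
                              noise_sd = 0.5,
                              n_replicates = c(2, 2, 1),
                              n_probes_per_gene = 2,
                              male_frac = c(0.64, 0.53, 0.52),
                              noneuro_frac = c(0.11, 0.08, 0),
                              age_range = c(18, 70),
                              seed = 1L) {
  cfg <- list(n_panels = as.integer(n_panels),
              panel_sizes = as.integer(panel_sizes),
              n_genes = as.integer(n_genes),
              n_snps_per_gene = as.integer(n_snps_per_gene),
              cis_window = cis_window, maf_range = maf_range,
              frac_cis_genes = frac_cis_genes, cis_h2_range = cis_h2_range,
              n_trans_regulators = as.integer(n_trans_regulators),
              trans_targets_per_regulator = as.integer(trans_targets_per_regulator),
              trans_h2 = trans_h2,
              age_effect_sd = age_effect_sd, sex_effect_sd = sex_effect_sd,
              frac_age_genes = frac_age_genes, frac_sex_genes = frac_sex_genes,
              n_confounders_per_panel = as.integer(n_confounders_per_panel),
              confounder_var_frac = confounder_var_frac,
              frac_confounded_genes = frac_confounded_genes,
              frac_probe_snp = rep_len(frac_probe_snp, n_panels),
              probe_artifact_delta = probe_artifact_delta,
              ld_decay = ld_decay, frac_imputed = frac_imputed,
              noise_sd = noise_sd,
              n_replicates = rep_len(as.integer(n_replicates), n_panels),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              male_frac = rep_len(male_frac, n_panels),
              noneuro_frac = rep_len(noneuro_frac, n_panels),
              age_range = age_range, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  assert_that(length(cfg$panel_sizes) == cfg$n_panels,
              "panel_sizes must have n_panels entries")
  assert_that(all(cfg$panel_sizes >= 2), "each panel needs >= 2 samples")
  props <- c(cfg$frac_cis_genes, cfg$frac_age_genes, cfg$frac_sex_genes,
             cfg$confounder_var_frac, cfg$frac_confounded_genes,
             cfg$frac_probe_snp, cfg$frac_imputed, cfg$trans_h2,
             cfg$cis_h2_range)
  assert_that(all(props >= 0 & props <= 1), "all proportions must lie in [0, 1]")
  assert_that(all(cfg$maf_range > 0 & cfg$maf_range <= 0.5),
              "maf_range must lie in (0, 0.5]")
  assert_that(cfg$ld_decay >= 0 && cfg$ld_decay < 1, "ld_decay must be in [0, 1)")
  assert_that(max(cfg$cis_h2_range) + cfg$confounder_var_frac + cfg$trans_h2 < 1,
              "cis, trans and confounder variance fractions must leave room for noise")
  invisible(cfg)
}

# Genome layout: genes spread over four autosomes plus chrX (which receives a
# majority of the sex-affected genes), spaced far enough apart that cis windows
# never overlap across genes.
build_gene_layout <- function(cfg) {
  ng <- cfg$n_genes
  sex_genes <- sort(sample.int(ng, round(cfg$frac_sex_genes * ng)))
  age_genes <- sort(sample.int(ng, round(cfg$frac_age_genes * ng)))
  on_x <- rep(FALSE, ng)
  if (length(sex_genes) > 1)
    on_x[sample(sex_genes, ceiling(0.6 * length(sex_genes)))] <- TRUE
  chroms <- character(ng)
  chroms[on_x] <- "X"
  chroms[!on_x] <- rep_len(c("1", "2", "3", "4"), sum(!on_x))
  spacing <- 5 * cfg$cis_window
  tss <- integer(ng)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    tss[idx] <- 10^6 + (seq_along(idx) - 1L) * spacing
  }
  data.frame(gene_id = sprintf("G%04d", seq_len(ng)), chrom = chroms,
             tss = tss, strand = sample(c("+", "-"), ng, replace = TRUE),
             is_sex_gene = seq_len(ng) %in% sex_genes,
             is_age_gene = seq_len(ng) %in% age_genes,
             stringsAsFactors = FALSE)
}

build_snp_layout <- function(cfg, genes) {
  half <- floor(0.8 * cfg$cis_window)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    pos <- sort(sample(seq(genes$tss[i] - half, genes$tss[i] + half),
                       cfg$n_snps_per_gene))
    data.frame(snp_id = sprintf("%s_s%02d", genes$gene_id[i],
                                seq_len(cfg$n_snps_per_gene)),
               gene_id = genes$gene_id[i], chrom = genes$chrom[i], pos = pos,
               freq = runif(cfg$n_snps_per_gene, cfg$maf_range[1],
                            cfg$maf_range[2]),
               stringsAsFactors = FALSE)
  })
  layout <- do.call(rbind, out)
  layout[order(layout$chrom, layout$pos), , drop = FALSE]
}

#' Simulate a genotype dosage panel
#'
#' Draws hard-call genotypes under Hardy-Weinberg equilibrium from per-SNP
#' allele frequencies, with adjacent-SNP linkage induced by first-order
#' haplotype copying (each haplotype allele is copied from the previous SNP
#' with probability `ld_decay`, else redrawn at its own frequency; copying
#' resets at chromosome boundaries). A fraction of SNPs is converted to
#' fractional dosages, emulating mean-imputed genotypes: the dosage is the
#' hard call shrunk toward `2 * freq` by a per-SNP quality factor in
#' `[0.7, 1]`, and those SNPs are flagged `imputed`.
#'
#' @param n_samples number of individuals (>= 2).
#' @param snp_layout data.frame with columns `snp_id`, `chrom`, `pos`, `freq`
#'   (allele frequency in (0, 0.5]); rows must be position-sorted within
#'   chromosome.
#' @param ld_decay copying probability in [0, 1).
#' @param frac_imputed fraction of SNPs reported as fractional dosages.
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample ids.
#'
#' @return A [genotype_matrix()]; `snp_meta$maf` is the empirical minor-allele
#'   frequency of the returned dosages.
#' @export
simulate_genotypes <- function(n_samples, snp_layout, ld_decay = 0.9,
                               frac_imputed = 0, seed = 1L,
                               sample_prefix = "S") {
  assert_that(n_samples >= 2, "n_samples must be >= 2, got %d", n_samples)
  assert_that(all(snp_layout$freq > 0 & snp_layout$freq <= 0.5),
              "allele frequencies must lie in (0, 0.5]")
  assert_that(ld_decay >= 0 && ld_decay < 1, "ld_decay must be in [0, 1)")
  with_seed(seed, {
    S <- nrow(snp_layout)
    f <- snp_layout$freq
    new_chrom <- c(TRUE, snp_layout$chrom[-1] != snp_layout$chrom[-S])
    # copy the latent uniform, not the allele: adjacent SNPs stay correlated
    # while every SNP keeps its exact marginal frequency
    hap <- function() {
      u <- matrix(0, n_samples, S)
      for (s in seq_len(S)) {
        fresh <- runif(n_samples)
        if (new_chrom[s]) u[, s] <- fresh
        else {
          copy <- runif(n_samples) < ld_decay
          u[, s] <- ifelse(copy, u[, s - 1L], fresh)
        }
      }
      matrix(as.integer(u < rep(f, each = n_samples)), n_samples, S)
    }
    g <- hap() + hap()
    dos <- g
    imputed <- rep(FALSE, S)
    if (frac_imputed > 0) {
      imp <- sample.int(S, round(frac_imputed * S))
      imputed[imp] <- TRUE
      q <- runif(length(imp), 0.7, 1)
      dos[, imp] <- sweep(sweep(g[, imp, drop = FALSE], 2, 2 * f[imp], "-"),
                          2, q, "*")
      dos[, imp] <- sweep(dos[, imp, drop = FALSE], 2, 2 * f[imp], "+")
    }
    fhat <- colMeans(dos) / 2
    meta <- data.frame(snp_id = snp_layout$snp_id, chrom = snp_layout$chrom,
                       pos = snp_layout$pos, ref = "A", alt = "G",
                       maf = pmin(fhat, 1 - fhat), imputed = imputed,
                       stringsAsFactors = FALSE)
    out <- genotype_matrix(dos, meta,
                           sample_ids = sprintf("%s%03d", sample_prefix,
                                                seq_len(n_samples)))
    # hard calls kept alongside: genetic effects on expression act on the
    # true genotype, while analyses see the (possibly shrunk) dosages
    out$hard <- g
    dimnames(out$hard) <- dimnames(out$dosages)
    out
  })
}

# Per-gene effect sizes and exact variance bookkeeping. Total per-gene variance
# T solves T * (1 - cis - trans - conf fractions) = demographic variance +
# noise_sd^2, so reported fractions sum to 1 exactly.
build_truth_genes <- function(cfg, genes, snp_layout, demo_design) {
  ng <- nrow(genes)
  cis_gene <- seq_len(ng) %in% sample.int(ng, round(cfg$frac_cis_genes * ng))
  cis_h2 <- ifelse(cis_gene, runif(ng, cfg$cis_h2_range[1], cfg$cis_h2_range[2]), 0)
  cis_snp <- rep(NA_character_, ng)
  for (i in which(cis_gene)) {
    cand <- snp_layout$snp_id[snp_layout$gene_id == genes$gene_id[i]]
    cis_snp[i] <- sample(cand, 1)
  }
  # trans regulators sit in autosomal genes; targets on other chromosomes
  trans_snp <- rep(NA_character_, ng); trans_h2 <- rep(0, ng)
  if (cfg$n_trans_regulators > 0) {
    reg_genes <- sample(which(genes$chrom == "1"),
                        min(cfg$n_trans_regulators, sum(genes$chrom == "1")))
    for (rg in reg_genes) {
      reg_snp <- sample(snp_layout$snp_id[snp_layout$gene_id == genes$gene_id[rg]], 1)
      targets <- sample(which(genes$chrom != genes$chrom[rg] & !cis_gene &
                                is.na(trans_snp)),
                        min(cfg$trans_targets_per_regulator,
                            sum(genes$chrom != genes$chrom[rg] & !cis_gene &
                                  is.na(trans_snp))))
      trans_snp[targets] <- reg_snp
      trans_h2[targets] <- cfg$trans_h2
    }
  }
  age_beta <- ifelse(genes$is_age_gene, rnorm(ng, 0, cfg$age_effect_sd), 0)
  sex_beta <- ifelse(genes$is_sex_gene, rnorm(ng, 0, cfg$sex_effect_sd), 0)
  confounded <- seq_len(ng) %in% sample.int(ng, round(cfg$frac_confounded_genes * ng))
  conf_frac <- ifelse(confounded & cfg$n_confounders_per_panel > 0,
                      cfg$confounder_var_frac, 0)

  v_age <- age_beta^2 * demo_design$var_age
  v_sex <- sex_beta^2 * demo_design$var_sex
  free <- 1 - cis_h2 - trans_h2 - conf_frac
  total_var <- (v_age + v_sex + cfg$noise_sd^2) / free
  fmap <- stats::setNames(snp_layout$freq, snp_layout$snp_id)
  snp_var <- function(id) ifelse(is.na(id), NA_real_,
                                 2 * fmap[id] * (1 - fmap[id]))
  cis_beta <- ifelse(cis_gene,
                     sample(c(-1, 1), ng, replace = TRUE) *
                       sqrt(cis_h2 * total_var / snp_var(cis_snp)), 0)
  trans_beta <- ifelse(trans_h2 > 0,
                       sample(c(-1, 1), ng, replace = TRUE) *
                         sqrt(trans_h2 * total_var / snp_var(trans_snp)), 0)
  data.frame(genes, cis_snp_id = cis_snp, cis_beta = cis_beta, cis_h2 = cis_h2,
             trans_snp_id = trans_snp, trans_beta = trans_beta,
             trans_h2 = trans_h2, age_beta = age_beta, sex_beta = sex_beta,
             conf_frac = conf_frac, total_var = total_var,
             demo_frac = (v_age + v_sex) / total_var,
             noise_frac = cfg$noise_sd^2 / total_var,
             baseline = rnorm(ng, 8, 1), stringsAsFactors = FALSE)
}

# Platform-specific probe map for one panel. Probes target alternating exons;
# artifact probes are relocated to cover one of the gene's SNPs, so the planted
# artifact variant always lies inside the probe interval.
build_probe_map <- function(cfg, panel_idx, genes, snp_layout) {
  ng <- nrow(genes)
  np <- cfg$n_probes_per_gene
  probe <- expand.grid(j = seq_len(np), gi = seq_len(ng))
  exon <- ((panel_idx + probe$j - 2L) %% 3L) + 1L
  start0 <- genes$tss[probe$gi] + (exon - 1L) * 1000L + 100L * probe$j
  pm <- data.frame(
    probe_id = sprintf("P%d_%s_p%d", panel_idx, genes$gene_id[probe$gi], probe$j),
    gene_id = genes$gene_id[probe$gi],
    exon_id = sprintf("%s_e%d", genes$gene_id[probe$gi], exon),
    chrom = genes$chrom[probe$gi], start = start0, end = start0 + 60L,
    strand = genes$strand[probe$gi], stringsAsFactors = FALSE)
  n_art <- round(cfg$frac_probe_snp[panel_idx] * nrow(pm))
  art <- rep(FALSE, nrow(pm)); art[sample.int(nrow(pm), n_art)] <- TRUE
  art_snp <- rep(NA_character_, nrow(pm))
  for (i in which(art)) {
    cand <- snp_layout[snp_layout$gene_id == pm$gene_id[i], ]
    k <- sample.int(nrow(cand), 1)
    art_snp[i] <- cand$snp_id[k]
    pm$start[i] <- cand$pos[k] - 31L   # variant inside [start, end)
    pm$end[i] <- pm$start[i] + 60L
  }
  pm$n_probe_snps <- as.integer(art)
  pm$artifact <- art
  pm$artifact_snp_id <- art_snp
  pm$artifact_delta <- ifelse(art, cfg$probe_artifact_delta, 0)
  pm$probe_offset <- rnorm(nrow(pm), 0, 0.25)
  pm
}

simulate_demographics <- function(cfg, panel_idx, sample_ids) {
  n <- length(sample_ids)
  sex <- ifelse(runif(n) < cfg$male_frac[panel_idx], "male", "female")
  pop <- ifelse(runif(n) < cfg$noneuro_frac[panel_idx], "AFR", "EUR")
  data.frame(sample_id = sample_ids,
             age = round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1),
             sex = sex,
             ancestry = ifelse(pop == "AFR", rnorm(n, 0.8, 0.1),
                               rnorm(n, 0, 0.05)),
             population = pop, stringsAsFactors = FALSE)
}

demo_design_variances <- function(cfg) {
  list(var_age = diff(cfg$age_range)^2 / 12,
       var_sex = cfg$male_frac[1] * (1 - cfg$male_frac[1]))
}

#' Simulate expression for one panel
#'
#' Inverts the covariate model: for probe `j` of gene `g` and sample `i`,
#' `value = baseline_g + offset_j + cis_beta_g * genotype + trans_beta_g *
#' genotype
#' + age_beta_g * age + sex_beta_g * male + loadings_g . scores_i
#' - artifact_delta_j * artifact_allele_count + replicate noise`. Genetic and
#' artifact terms act on the hard-call genotypes (the true alleles); the
#' analysis-facing dosage matrix may carry shrunk imputed values. Technical
#' replicates share the per-sample signal and differ only in measurement
#' noise. Confounder scores/loadings are taken from `truth$confounders` for
#' the named panel.
#'
#' @param genotypes a [genotype_matrix()] for this panel's samples.
#' @param demographics demographics data.frame for the same samples.
#' @param truth truth table from [simulate_multi_study()] (or built the same
#'   way); must contain this panel's probe map and confounders.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param panel panel index (selects probe map, confounders, replicate count).
#'
#' @return An [expression_matrix()] with replicate columns when configured.
#' @export
simulate_expression <- function(genotypes, demographics, truth, config,
                                seed = 1L, panel = 1L) {
  pm <- truth$probes[[panel]]
  genes <- truth$genes
  assert_that(all(stats::na.omit(c(genes$cis_snp_id, genes$trans_snp_id,
                                   pm$artifact_snp_id)) %in%
                    genotypes$snp_meta$snp_id),
              "truth refers to SNPs absent from the genotype matrix")
  n <- length(genotypes$sample_ids)
  assert_that(identical(demographics$sample_id, genotypes$sample_ids),
              "demographics and genotypes must list the same samples in order")
  with_seed(seed, {
    dos <- genotypes$hard %||% genotypes$dosages
    gi <- match(pm$gene_id, genes$gene_id)
    male <- as.numeric(demographics$sex == "male")
    # per-gene sample signal (samples x genes)
    sig <- matrix(0, n, nrow(genes))
    for (k in seq_len(nrow(genes))) {
      mu <- genes$baseline[k] +
        genes$age_beta[k] * demographics$age + genes$sex_beta[k] * male
      if (!is.na(genes$cis_snp_id[k]))
        mu <- mu + genes$cis_beta[k] * dos[, genes$cis_snp_id[k]]
      if (!is.na(genes$trans_snp_id[k]))
        mu <- mu + genes$trans_beta[k] * dos[, genes$trans_snp_id[k]]
      sig[, k] <- mu
    }
    conf <- truth$confounders[[panel]]
    if (!is.null(conf) && ncol(conf$scores) > 0)
      sig <- sig + conf$scores %*% t(conf$loadings)
    nrep <- config$n_replicates[panel]
    cols <- n * nrep
    vals <- matrix(0, nrow(pm), cols)
    sample_ids <- rep(genotypes$sample_ids, each = nrep)
    replicate_ids <- if (nrep > 1) rep(sprintf("r%d", seq_len(nrep)), n) else NULL
    for (p in seq_len(nrow(pm))) {
      base <- sig[, gi[p]] + pm$probe_offset[p]
      if (pm$artifact[p])
        base <- base - pm$artifact_delta[p] * dos[, pm$artifact_snp_id[p]]
      vals[p, ] <- rep(base, each = nrep) +
        rnorm(cols, 0, config$noise_sd)
    }
    expression_matrix(vals, pm[, c("probe_id", "gene_id", "exon_id", "chrom",
                                   "start", "end", "strand", "n_probe_snps")],
                      sample_ids = sample_ids, replicate_ids = replicate_ids)
  })
}

#' Simulate a multi-study eQTL dataset with known ground truth
#'
#' Generates `n_panels` disjoint cohorts sharing one gene/SNP layout and one
#' set of genetic and demographic effects, with panel-specific sample draws,
#' hidden confounders and platform probe maps (different exons targeted and
#' different probe-SNP artifact fractions per platform).
#'
#' @param config a [simulation_config()].
#'
#' @return A list with `panels` (list of [study_panel()]) and `truth`, a
#'   truth table holding `genes` (per-gene effects and exact variance
#'   fractions), `probes` (per-panel probe maps with artifact flags),
#'   `confounders` (per-panel loadings and scores), `snp_layout`, and the
#'   demographic design variances used for bookkeeping.
#' @export
simulate_multi_study <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, {
    genes <- build_gene_layout(config)
    snp_layout <- build_snp_layout(config, genes)
    design <- demo_design_variances(config)
    tg <- build_truth_genes(config, genes, snp_layout, design)
    probes <- lapply(seq_len(config$n_panels), function(k)
      build_probe_map(config, k, genes, snp_layout))
    sub_seeds <- sample.int(2^31 - 1, 3 * config$n_panels)
    confounders <- vector("list", config$n_panels)
    panels <- vector("list", config$n_panels)
    for (k in seq_len(config$n_panels)) {
      nk <- config$panel_sizes[k]
      geno <- simulate_genotypes(nk, snp_layout, ld_decay = config$ld_decay,
                                 frac_imputed = config$frac_imputed,
                                 seed = sub_seeds[3 * k - 2],
                                 sample_prefix = sprintf("P%d_S", k))
      dem <- with_seed(sub_seeds[3 * k - 1],
                       simulate_demographics(config, k, geno$sample_ids))
      kc <- config$n_confounders_per_panel
      load <- matrix(0, nrow(tg), kc)
      if (kc > 0) {
        for (g in which(tg$conf_frac > 0)) {
          raw <- rnorm(kc)
          load[g, ] <- raw * sqrt(tg$conf_frac[g] * tg$total_var[g] /
                                    sum(raw^2))
        }
      }
      confounders[[k]] <- list(loadings = load,
                               scores = matrix(rnorm(nk * kc), nk, kc))
      truth_k <- list(genes = tg, probes = probes,
                      confounders = confounders, snp_layout = snp_layout)
      expr <- simulate_expression(geno, dem, truth_k, config,
                                  seed = sub_seeds[3 * k], panel = k)
      panels[[k]] <- study_panel(sprintf("panel%d", k), geno, expr, dem,
                                 platform = sprintf("platform%d", k))
    }
    truth <- list(genes = tg, probes = probes, confounders = confounders,
                  snp_layout = snp_layout, demo_design = design,
                  config = config)
    list(panels = panels, truth = truth)
  })
}

#' Simulate a haplotype reporter (luciferase) plate
#'
#' Luminescence = haplotype mean + per-preparation random intercept +
#' residual noise, mirroring a transient-transfection design in which each
#' construct is prepared several times (default 3 vector preparations) and
#' each preparation transfected in several replicate wells (default 4, i.e.
#' 12 measurements per haplotype).
#'
#' @param haplotype_effects named numeric vector of haplotype mean shifts.
#' @param n_preps vector preparations per haplotype (>= 1).
#' @param n_reps transfection replicates per preparation (>= 1).
#' @param prep_sd SD of the per-preparation random intercept (>= 0).
#' @param residual_sd residual SD (>= 0).
#' @param seed integer seed.
#' @param region_id label for the assayed region.
#'
#' @return data.frame of class `reporter_plate` with columns `region_id`,
#'   `haplotype_id`, `prep_id`, `replicate_index`, `luminescence`.
#' @export
simulate_reporter <- function(haplotype_effects, n_preps = 3, n_reps = 4,
                              prep_sd = 0.1, residual_sd = 0.1, seed = 1L,
                              region_id = "R1") {
  assert_that(n_preps >= 1 && n_reps >= 1, "n_preps and n_reps must be >= 1")
  assert_that(prep_sd >= 0 && residual_sd >= 0, "SDs must be non-negative")
  assert_that(!is.null(names(haplotype_effects)) &&
                length(haplotype_effects) >= 1,
              "haplotype_effects must be a named vector")
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(haplotype_effects), function(h) {
      prep_int <- rnorm(n_preps, 0, prep_sd)
      data.frame(region_id = region_id, haplotype_id = h,
                 prep_id = sprintf("%s_prep%d", h, rep(seq_len(n_preps),
                                                       each = n_reps)),
                 replicate_index = rep(seq_len(n_reps), n_preps),
                 luminescence = haplotype_effects[[h]] +
                   rep(prep_int, each = n_reps) +
                   rnorm(n_preps * n_reps, 0, residual_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    class(out) <- c("reporter_plate", "data.frame")
    out
  })
}
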