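# Single-SNP association scans.
#
# The Bayes factor is the conjugate normal--inverse-gamma marginal likelihood
# ratio of y = mu + a g + e (a ~ N(0, sigma_a^2 sigma^2), flat prior on mu,
# Jeffreys prior on sigma^2) against the intercept-only model, averaged over a
# grid of prior effect scales. With centered sums Syy, Sgy, Sgg the ratio is
# closed form:
#
#   BF(sigma_a) = (1 + sigma_a^2 Sgg)^(-1/2) * (Syy / RSS_b)^((n-1)/2),
#   RSS_b = Syy - Sgy^2 / (Sgg + sigma_a^(-2)),
#
# i.e. a ridge-shrunk residual sum of squares. Reported as log10 throughout.

#' Bayes-factor prior specification
#'
#' @param sigma_a grid of prior effect scales (default `c(0.05, 0.2, 0.4)`).
#' @param weights prior weights (default equal); must sum to 1.
#' @return list of class `bf_prior_spec`.
#' @export
bf_prior_spec <- function(sigma_a = c(0.05, 0.2, 0.4),
                          weights = rep(1 / length(sigma_a), length(sigma_a))) {
  assert_that(all(sigma_a > 0), "prior scales must be positive")
  assert_that(abs(sum(weights) - 1) < 1e-8, "prior weights must sum to 1")
  structure(list(sigma_a = sigma_a, weights = weights), class = "bf_prior_spec")
}

#' Single-SNP Bayes factor
#'
#' log10 Bayes factor of the additive single-SNP model against the
#' intercept-only null, averaged over the prior grid. Location/scale
#' invariant in `y` because the effect prior scales with the residual SD.
#'
#' @param y phenotype vector (centered internally).
#' @param g dosage vector (must vary; `n >= 3`).
#' @param priors a [bf_prior_spec()].
#'
#' @return log10 BF (scalar).
#' @export
single_snp_bf <- function(y, g, priors = bf_prior_spec()) {
  n <- length(y)
  assert_that(n == length(g), "y and g lengths differ")
  assert_that(n >= 3, "need n >= 3")
  gc <- g - mean(g)
  Sgg <- sum(gc^2)
  assert_that(Sgg > 0, "SNP is monomorphic in sample")
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sgy <- sum(gc * yc)
  log10bf <- vapply(priors$sigma_a, function(sa) {
    rssb <- Syy - Sgy^2 / (Sgg + sa^-2)
    (-0.5 * log(1 + sa^2 * Sgg) + (n - 1) / 2 * (log(Syy) - log(rssb))) /
      log(10)
  }, numeric(1))
  log10_weighted_sum(log10bf, priors$weights)
}

#' Single-SNP least-squares association
#'
#' Ordinary least-squares slope of `y` on `g` with the two-sided t-test.
#'
#' @inheritParams single_snp_bf
#' @return list with `beta`, `se`, `t`, `p`.
#' @export
single_snp_lm <- function(y, g) {
  n <- length(y)
  assert_that(n == length(g), "y and g lengths differ")
  assert_that(n >= 3, "need n >= 3")
  gc <- g - mean(g)
  Sgg <- sum(gc^2)
  assert_that(Sgg > 0, "SNP is monomorphic in sample")
  yc <- y - mean(y)
  beta <- sum(gc * yc) / Sgg
  rss <- sum(yc^2) - beta^2 * Sgg
  se <- sqrt(max(rss, 0) / (n - 2) / Sgg)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, t = tval, p = max(p, .Machine$double.xmin))
}

# Vectorized association of one phenotype against many SNPs.
# Returns a data.frame of per-SNP statistics.
assoc_many <- function(y, G, priors) {
  n <- length(y)
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Gc <- sweep(G, 2, colMeans(G))
  Sgg <- colSums(Gc^2)
  Sgy <- as.numeric(crossprod(Gc, yc))
  ok <- Sgg > 0
  beta <- ifelse(ok, Sgy / Sgg, NA_real_)
  rss <- Syy - beta^2 * Sgg
  se <- sqrt(pmax(rss, 0) / (n - 2) / Sgg)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  lb <- matrix(0, length(Sgg), length(priors$sigma_a))
  for (k in seq_along(priors$sigma_a)) {
    sa <- priors$sigma_a[k]
    rssb <- Syy - Sgy^2 / (Sgg + sa^-2)
    lb[, k] <- (-0.5 * log1p(sa^2 * Sgg) +
                  (n - 1) / 2 * (log(Syy) - log(rssb))) / log(10)
  }
  mx <- apply(lb, 1, max)
  log10_bf <- mx + log10(rowSums(sweep(10^(lb - mx), 2, priors$weights, "*")))
  data.frame(log10_bf = ifelse(ok, log10_bf, NA_real_), beta = beta, se = se,
             t = tval, p = p, stringsAsFactors = FALSE)
}

# Deterministic best-SNP pick: max log10 BF, ties broken by genomic
# coordinate then lexicographic snp id.
best_row <- function(tab) {
  o <- order(-tab$log10_bf, tab$pos, tab$snp_id)
  tab[o[1], , drop = FALSE]
}

gene_table <- function(adjusted) {
  Y <- if (inherits(adjusted, "adjusted_phenotypes")) adjusted$residuals
       else as.matrix(adjusted)
  Y
}

scan_core <- function(adjusted, genotypes, genes, eligible_fun, priors,
                      maf_min, keep_all, cis_flag, window = NA) {
  Y <- gene_table(adjusted)
  shared <- intersect(colnames(Y), genotypes$sample_ids)
  assert_that(length(shared) >= 3, "fewer than 3 shared samples")
  if (length(shared) < ncol(Y))
    message(sprintf("scan: intersecting samples (%d of %d phenotype columns)",
                    length(shared), ncol(Y)))
  Y <- Y[, shared, drop = FALSE]
  G <- genotypes$dosages[shared, , drop = FALSE]
  meta <- genotypes$snp_meta
  maf_ok <- meta$maf >= maf_min
  best <- vector("list", nrow(Y))
  full <- if (keep_all) vector("list", nrow(Y)) else NULL
  gene_ids <- intersect(rownames(Y), genes$gene_id)
  for (gid in gene_ids) {
    gi <- match(gid, genes$gene_id)
    sel <- eligible_fun(meta, genes[gi, , drop = FALSE]) & maf_ok
    rec0 <- data.frame(gene_id = gid, snp_id = NA_character_,
                       chrom = NA_character_, pos = NA_integer_,
                       log10_bf = NA_real_, beta = NA_real_, se = NA_real_,
                       t = NA_real_, p = NA_real_, maf = NA_real_,
                       imputed = NA, tss_distance = NA_real_, cis = cis_flag,
                       n_snps_tested = 0L, stringsAsFactors = FALSE)
    if (!any(sel)) { best[[gid]] <- rec0; next }
    st <- assoc_many(Y[gid, ], G[, sel, drop = FALSE], priors)
    ok <- !is.na(st$log10_bf)
    if (!any(ok)) { best[[gid]] <- rec0; next }
    tab <- data.frame(gene_id = gid, snp_id = meta$snp_id[sel],
                      chrom = meta$chrom[sel], pos = meta$pos[sel],
                      st, maf = meta$maf[sel], imputed = meta$imputed[sel],
                      tss_distance = tss_distance(meta$pos[sel],
                                                  genes$tss[gi],
                                                  genes$strand[gi]),
                      cis = cis_flag, stringsAsFactors = FALSE)[ok, ,
                                                                drop = FALSE]
    if (keep_all) full[[gid]] <- tab
    b <- best_row(tab)
    b$n_snps_tested <- nrow(tab)
    best[[gid]] <- b
  }
  best_df <- do.call(rbind, best[gene_ids])
  rownames(best_df) <- NULL
  structure(list(best = best_df,
                 per_snp = if (keep_all) do.call(rbind, full) else NULL,
                 mode = if (cis_flag) "cis" else "trans",
                 priors = priors, maf_min = maf_min, window = window,
                 n_samples = length(shared)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s scan: %d genes, n = %d%s\n", x$mode,
              nrow(x$best), x$n_samples,
              if (!is.na(x$window)) sprintf(", window = %g bp", x$window) else ""))
  invisible(x)
}

#' Cis eQTL scan
#'
#' For each gene, tests every SNP with `|TSS distance| < window` and
#' `MAF >= maf_min`, recording the Bayes factor and least-squares statistics,
#' and selects the best SNP by log10 BF (ties broken by genomic coordinate,
#' then SNP id). Samples are intersected between the phenotype and genotype
#' matrices. Genes without an eligible SNP are kept with missing statistics.
#'
#' @param adjusted an `adjusted_phenotypes` object (or genes x samples
#'   matrix with gene ids as rownames).
#' @param genotypes a [genotype_matrix()].
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param window cis window in bp from the TSS (default 250000, exclusive).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param priors a [bf_prior_spec()].
#' @param keep_all also return the full per-SNP table.
#'
#' @return list of class `scan_result` with `best` (one row per gene) and
#'   optionally `per_snp`.
#' @export
cis_scan <- function(adjusted, genotypes, genes, window = 250000,
                     maf_min = 0.01, priors = bf_prior_spec(),
                     keep_all = FALSE) {
  eligible <- function(meta, gene)
    meta$chrom == gene$chrom & abs(meta$pos - gene$tss) < window
  scan_core(adjusted, genotypes, genes, eligible, priors, maf_min, keep_all,
            cis_flag = TRUE, window = window)
}

#' Trans eQTL scan
#'
#' As [cis_scan()], but tests SNPs on chromosomes other than the gene's.
#'
#' @inheritParams cis_scan
#' @return list of class `scan_result`.
#' @export
trans_scan <- function(adjusted, genotypes, genes, maf_min = 0.01,
                       priors = bf_prior_spec(), keep_all = FALSE) {
  eligible <- function(meta, gene) meta$chrom != gene$chrom
  scan_core(adjusted, genotypes, genes, eligible, priors, maf_min, keep_all,
            cis_flag = FALSE)
}

#' Association statistics for fixed gene-SNP pairs
#'
#' Computes the replication-panel statistics for a list of discovery
#' gene-SNP pairs: the least-squares coefficient, t-test p-value and log10 BF
#' of exactly the named SNP against the named gene. Pairs whose SNP (or gene)
#' is absent, or whose SNP is monomorphic in this panel, are flagged
#' untested.
#'
#' @param pairs data.frame with `gene_id` and `snp_id`.
#' @param adjusted adjusted phenotypes of the replication panel.
#' @param genotypes the replication panel's [genotype_matrix()].
#' @param priors a [bf_prior_spec()].
#'
#' @return data.frame with `gene_id`, `snp_id`, `beta`, `se`, `p`,
#'   `log10_bf`, `tested`.
#' @export
pair_association <- function(pairs, adjusted, genotypes,
                             priors = bf_prior_spec()) {
  Y <- gene_table(adjusted)
  shared <- intersect(colnames(Y), genotypes$sample_ids)
  Y <- Y[, shared, drop = FALSE]
  G <- genotypes$dosages[shared, , drop = FALSE]
  out <- data.frame(gene_id = pairs$gene_id, snp_id = pairs$snp_id,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    log10_bf = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]; sid <- pairs$snp_id[i]
    if (is.na(sid) || !(gid %in% rownames(Y)) || !(sid %in% colnames(G)))
      next
    g <- G[, sid]
    if (stats::var(g) == 0) next
    fit <- single_snp_lm(Y[gid, ], g)
    out$beta[i] <- fit$beta; out$se[i] <- fit$se; out$p[i] <- fit$p
    out$log10_bf[i] <- single_snp_bf(Y[gid, ], g, priors)
    out$tested[i] <- TRUE
  }
  out
}
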