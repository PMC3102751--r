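# Genotype and expression quality control.
#
# All internal intervals are 0-based half-open; VCF positions are converted on
# read. Filters run in the fixed order call-rate -> HWE -> MAF, and a SNP is
# counted against the first filter it fails, so the QC report reconciles
# exactly.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided conditional exact test on genotype counts. With allele counts
#' fixed, every heterozygote count `h` of the same parity as the observed one
#' has probability proportional to `n! / (nAA! nAB! nBB!) * 2^h`; the p-value
#' sums the probabilities of all outcomes no more probable than the observed
#' one (including it).
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, total >= 1).
#'
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "genotype counts must be non-negative integers")
  n <- sum(counts)
  assert_that(n >= 1, "all-zero genotype counts")
  nA <- 2 * n_AA + n_AB          # minor-allele copies (either allele works)
  h_values <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  log_p <- vapply(h_values, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  p_obs <- p[match(n_AB, h_values)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Genotype QC filters
#'
#' Removes SNPs failing, in order: call rate (more than `miss_max` missing),
#' Hardy-Weinberg equilibrium (exact test p below `hwe_alpha`, evaluated on
#' hard-call genotypes only; fractional dosages are exempt), and minor allele
#' frequency below `maf_min`. Each SNP is counted against the first filter it
#' fails. Survivors are mean-imputed per SNP.
#'
#' @param g a [genotype_matrix()]; missing calls are `NA` dosages and/or
#'   entries of `g$mask`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum missing fraction (default 0.10).
#' @param hwe_alpha HWE exact-test threshold (default 0.001).
#'
#' @return list with the filtered [genotype_matrix()] and a `qc_report`
#'   (counts, per-filter SNP id lists, parameters).
#' @export
filter_genotypes <- function(g, maf_min = 0.01, miss_max = 0.10,
                             hwe_alpha = 0.001) {
  dos <- g$dosages
  miss <- is.na(dos)
  if (!is.null(g$mask)) miss <- miss | g$mask
  miss_frac <- colMeans(miss)
  fail_call <- miss_frac > miss_max

  hard <- !g$snp_meta$imputed
  fail_hwe <- rep(FALSE, ncol(dos))
  for (j in which(hard & !fail_call)) {
    x <- dos[!miss[, j], j]
    if (!length(x) || any(x != round(x))) next
    p <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    fail_hwe[j] <- p < hwe_alpha
  }

  fhat <- colMeans(ifelse(miss, NA, dos), na.rm = TRUE) / 2
  maf <- pmin(fhat, 1 - fhat)
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_maf[is.na(maf)] <- TRUE

  first_fail <- rep("pass", ncol(dos))
  first_fail[fail_maf] <- "maf"
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_call] <- "callrate"
  keep <- first_fail == "pass"
  assert_that(any(keep), "no SNPs survive QC")

  out <- dos[, keep, drop = FALSE]
  mo <- miss[, keep, drop = FALSE]
  for (j in which(colSums(mo) > 0))
    out[mo[, j], j] <- mean(out[!mo[, j], j])
  meta <- g$snp_meta[keep, , drop = FALSE]
  meta$maf <- maf[keep]
  ids <- g$snp_meta$snp_id
  report <- structure(list(
    n_snps_in = ncol(dos),
    n_removed_callrate = sum(first_fail == "callrate"),
    n_removed_hwe = sum(first_fail == "hwe"),
    n_removed_maf = sum(first_fail == "maf"),
    n_snps_out = sum(keep),
    removed_callrate = ids[first_fail == "callrate"],
    removed_hwe = ids[first_fail == "hwe"],
    removed_maf = ids[first_fail == "maf"],
    parameters = list(maf_min = maf_min, miss_max = miss_max,
                      hwe_alpha = hwe_alpha)), class = "qc_report")
  list(genotypes = genotype_matrix(out, meta, sample_ids = g$sample_ids),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d SNPs in; removed %d (call rate > %g), ",
                     "%d (HWE p < %g), %d (MAF < %g); %d out\n"),
              x$n_snps_in, x$n_removed_callrate, x$parameters$miss_max,
              x$n_removed_hwe, x$parameters$hwe_alpha, x$n_removed_maf,
              x$parameters$maf_min, x$n_snps_out))
  invisible(x)
}

#' Infer sample sex from Y-linked expression and X heterozygosity
#'
#' 2-means clustering on (mean Y-linked probe expression, X-linked
#' heterozygosity rate); the cluster with higher Y expression is called male
#' (or, lacking Y probes, the cluster with lower X heterozygosity). Samples
#' whose call disagrees with the annotated sex are flagged.
#'
#' @param panel a [study_panel()].
#' @param y_linked_probes probe ids used for the Y-expression feature.
#' @param x_linked_snps SNP ids used for the X-heterozygosity feature.
#'
#' @return data.frame with `sample_id`, `inferred_sex`, `annotated_sex`,
#'   `mismatch`; inferred sex is `"indeterminate"` on degenerate features.
#' @export
infer_sex <- function(panel, y_linked_probes = NULL, x_linked_snps = NULL) {
  samples <- panel$genotypes$sample_ids
  assert_that(length(samples) >= 2, "need at least 2 samples")
  feats <- NULL
  if (length(y_linked_probes)) {
    expr <- panel$expression
    v <- expr$values[expr$probe_meta$probe_id %in% y_linked_probes, ,
                     drop = FALSE]
    ymean <- tapply(colMeans(v), expr$sample_ids, mean)[samples]
    feats <- cbind(feats, y_expr = as.numeric(ymean))
  }
  if (length(x_linked_snps)) {
    d <- panel$genotypes$dosages[, colnames(panel$genotypes$dosages) %in%
                                   x_linked_snps, drop = FALSE]
    het <- rowMeans(abs(d - 1) < 0.5)
    feats <- cbind(feats, x_het = het)
  }
  assert_that(!is.null(feats), "need Y-linked probes or X-linked SNPs")
  ann <- panel$demographics$sex[match(samples, panel$demographics$sample_id)]
  scaled <- apply(feats, 2, function(col)
    if (stats::sd(col) > 0) (col - mean(col)) / stats::sd(col) else col * 0)
  if (all(apply(feats, 2, stats::sd) == 0) || nrow(unique(scaled)) < 2) {
    return(data.frame(sample_id = samples, inferred_sex = "indeterminate",
                      annotated_sex = ann, mismatch = TRUE,
                      stringsAsFactors = FALSE))
  }
  km <- stats::kmeans(scaled, centers = 2, nstart = 10)
  male_cluster <- if ("y_expr" %in% colnames(feats)) {
    which.max(tapply(feats[, "y_expr"], km$cluster, mean))
  } else {
    which.min(tapply(feats[, "x_het"], km$cluster, mean))
  }
  call <- ifelse(km$cluster == male_cluster, "male", "female")
  data.frame(sample_id = samples, inferred_sex = call, annotated_sex = ann,
             mismatch = call != ann, stringsAsFactors = FALSE)
}

#' Annotate probes with overlapping variants
#'
#' Interval join between probe intervals (0-based half-open) and a variant
#' catalog, with optional flanking slack. Offsets are measured in bp from the
#' probe's 5' end (the leftmost base for + strand probes, the rightmost for -
#' strand).
#'
#' @param probes data.frame with `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param variants data.frame with `variant_id`, `chrom`, `pos` (1-based, as
#'   in VCF), `ref`, `alt` (alleles optional).
#' @param flank bp of flank to include on both sides (default 0).
#'
#' @return list of class `probe_snp_annotation`: `overlaps` data.frame
#'   (`probe_id`, `variant_id`, `offset`, `ref`, `alt`) and `n_probe_snps`
#'   named per probe.
#' @export
annotate_probe_snps <- function(probes, variants, flank = 0) {
  miss <- setdiff(unique(variants$chrom), unique(probes$chrom))
  if (length(miss) && nrow(probes))
    message("variant chromosomes absent from probes: ",
            paste(miss, collapse = ", "))
  pr <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(start = probes$start + 1 - flank,
                     end = probes$end + flank))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(pr, vr)
  pi <- S4Vectors::queryHits(hits); vi <- S4Vectors::subjectHits(hits)
  v0 <- variants$pos[vi] - 1L                      # 0-based variant coordinate
  offset <- ifelse(probes$strand[pi] == "-",
                   probes$end[pi] - 1L - v0, v0 - probes$start[pi])
  ov <- data.frame(probe_id = probes$probe_id[pi],
                   variant_id = variants$variant_id[vi],
                   offset = as.integer(offset),
                   ref = variants$ref[vi] %||% NA,
                   alt = variants$alt[vi] %||% NA,
                   stringsAsFactors = FALSE)
  ov <- ov[order(match(ov$probe_id, probes$probe_id), ov$offset), , drop = FALSE]
  rownames(ov) <- NULL
  counts <- table(factor(ov$probe_id, levels = probes$probe_id))
  structure(list(overlaps = ov,
                 n_probe_snps = stats::setNames(as.integer(counts),
                                                probes$probe_id),
                 flank = flank),
            class = "probe_snp_annotation")
}

#' Cluster probes of a gene into probesets
#'
#' Per gene, probes are hierarchically clustered (complete linkage) on the
#' distance `1 - Pearson correlation` and the dendrogram is cut at height 0.5,
#' so every within-probeset pairwise correlation is at least 0.5. Probeset
#' expression is the per-column mean of member probes. Constant (zero
#' variance) probes become singleton probesets with a warning.
#'
#' @param expr an [expression_matrix()] (probe_meta$gene_id provides the
#'   grouping; probes with missing gene ids are dropped).
#' @param cut_height dendrogram cut height (default 0.5).
#'
#' @return list of class `probeset_map`: `map` data.frame (`probeset_id`,
#'   `probe_id`, `gene_id`), `min_internal_cor` per probeset, and `expr`, an
#'   [expression_matrix()] of probeset-level values.
#' @export
cluster_probes_to_probesets <- function(expr, cut_height = 0.5) {
  assert_that(ncol(expr$values) >= 2, "need at least 2 columns")
  pm <- expr$probe_meta
  keep <- !is.na(pm$gene_id)
  pm <- pm[keep, , drop = FALSE]
  vals <- expr$values[keep, , drop = FALSE]
  map <- NULL
  mic <- numeric(0)
  warn_const <- FALSE
  for (g in unique(pm$gene_id)) {
    idx <- which(pm$gene_id == g)
    if (length(idx) == 1) {
      cl <- stats::setNames(1L, pm$probe_id[idx])
    } else {
      v <- vals[idx, , drop = FALSE]
      const <- apply(v, 1, stats::sd) == 0
      if (any(const)) warn_const <- TRUE
      cl <- rep(NA_integer_, length(idx))
      names(cl) <- pm$probe_id[idx]
      live <- which(!const)
      if (length(live) >= 2) {
        r <- stats::cor(t(v[live, , drop = FALSE]))
        hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
        cl[live] <- stats::cutree(hc, h = cut_height)
      } else if (length(live) == 1) cl[live] <- 1L
      nxt <- max(cl, 0L, na.rm = TRUE)
      for (i in which(is.na(cl))) { nxt <- nxt + 1L; cl[i] <- nxt }
    }
    ids <- sprintf("%s_ps%d", g, cl)
    map <- rbind(map, data.frame(probeset_id = ids, probe_id = names(cl),
                                 gene_id = g, stringsAsFactors = FALSE))
  }
  if (warn_const) warnf("constant probes assigned singleton probesets")
  ps_ids <- unique(map$probeset_id)
  out <- matrix(0, length(ps_ids), ncol(vals),
                dimnames = list(ps_ids, colnames(vals)))
  mic <- stats::setNames(rep(1, length(ps_ids)), ps_ids)
  meta_rows <- vector("list", length(ps_ids))
  for (i in seq_along(ps_ids)) {
    members <- map$probe_id[map$probeset_id == ps_ids[i]]
    mi <- match(members, pm$probe_id)
    out[i, ] <- colMeans(vals[mi, , drop = FALSE])
    if (length(mi) > 1) {
      r <- stats::cor(t(vals[mi, , drop = FALSE]))
      mic[i] <- min(r[upper.tri(r)])
    }
    m1 <- pm[mi[1], , drop = FALSE]
    m1$probe_id <- ps_ids[i]
    m1$start <- min(pm$start[mi]); m1$end <- max(pm$end[mi])
    m1$n_probe_snps <- sum(pm$n_probe_snps[mi])
    meta_rows[[i]] <- m1
  }
  meta <- do.call(rbind, meta_rows)
  structure(list(map = map, min_internal_cor = mic,
                 expr = expression_matrix(out, meta,
                                          sample_ids = expr$sample_ids,
                                          replicate_ids = expr$replicate_ids)),
            class = "probeset_map")
}

# Dixon r10 critical values, one-sided alpha = 0.05. n = 3..30 from the
# classical table; n > 30 from a 2e5-draw Gaussian calibration grid,
# interpolated linearly in 1/n.
dixon_crit_table <- list(
  n = c(3:30, 35, 40, 50, 60, 80, 100, 150, 200, 300, 500),
  crit = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412, 0.392,
           0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313, 0.306, 0.300,
           0.295, 0.290, 0.285, 0.281, 0.277, 0.273, 0.269, 0.266, 0.263,
           0.260, 0.2473, 0.2372, 0.2211, 0.2107, 0.1957, 0.1845, 0.1690,
           0.1589, 0.1460, 0.1334))

dixon_critical_value <- function(n) {
  tab <- dixon_crit_table
  if (n <= 30) return(tab$crit[match(n, tab$n)])
  stats::approx(1 / tab$n, tab$crit, xout = 1 / n, rule = 2)$y
}

#' Dixon outlier screen for per-array metrics
#'
#' Computes the Dixon Q ratio (gap to nearest neighbour over range) for the
#' smallest and largest value of each metric and flags an array when Q exceeds
#' the one-sided critical value at `alpha = 0.05`. Arrays flagged on any
#' metric are reported (advisory, not auto-removal).
#'
#' @param array_metrics numeric vector, or matrix/data.frame with one column
#'   per metric and one row per array.
#'
#' @return logical vector of flags (one per array); all `FALSE` when fewer
#'   than 4 arrays.
#' @export
dixon_outlier_flag <- function(array_metrics) {
  m <- as.matrix(array_metrics)
  n <- nrow(m)
  flags <- rep(FALSE, n)
  if (n < 4) return(flags)
  crit <- dixon_critical_value(n)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    s <- x[o]
    rng <- s[n] - s[1]
    if (rng == 0) next
    if ((s[2] - s[1]) / rng > crit) flags[o[1]] <- TRUE
    if ((s[n] - s[n - 1]) / rng > crit) flags[o[n]] <- TRUE
  }
  flags
}

#' Signed SNP-to-TSS distance
#'
#' Negative distances are 5' of the gene in its transcriptional orientation:
#' for + strand genes the distance is `snp_pos - tss`, for - strand genes
#' `tss - snp_pos`.
#'
#' @param snp_pos 1-based SNP position(s).
#' @param tss 1-based TSS position(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @param snp_chrom,gene_chrom optional chromosome labels; a mismatch errors.
#'
#' @return signed distance(s) in bp.
#' @export
tss_distance <- function(snp_pos, tss, strand, snp_chrom = NULL,
                         gene_chrom = NULL) {
  if (!is.null(snp_chrom) && !is.null(gene_chrom))
    assert_that(all(snp_chrom == gene_chrom),
                "SNP and gene must be on the same chromosome")
  ifelse(strand == "-", tss - snp_pos, snp_pos - tss)
}
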