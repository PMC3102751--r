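make_geno <- function(dosages, pos = NULL, imputed = NULL, mask = NULL,
                      chrom = "1") {
  dosages <- as.matrix(dosages)
  S <- ncol(dosages)
  meta <- data.frame(snp_id = sprintf("s%02d", seq_len(S)), chrom = chrom,
                     pos = pos %||% seq_len(S) * 10L, ref = "A", alt = "G",
                     maf = colMeans(dosages, na.rm = TRUE) / 2,
                     imputed = imputed %||% rep(FALSE, S),
                     stringsAsFactors = FALSE)
  genotype_matrix(dosages, meta,
                  sample_ids = sprintf("S%03d", seq_len(nrow(dosages))),
                  mask = mask)
}

test_that("exact HWE test matches hand-enumerated cases", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  # all heterozygotes at n = 2: P(h = 2) = 2/3 > P(h = 0), p = 1
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
})

test_that("exact HWE test equals the enumeration oracle on random counts", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    nAB <- sample(0:n, 1)
    nAA <- sample(0:(n - nAB), 1)
    nBB <- n - nAB - nAA
    expect_equal(hwe_exact_test(nAA, nAB, nBB), hwe_oracle(nAA, nAB, nBB),
                 tolerance = 1e-12)
  }
})

test_that("genotype filters apply in order with exact bookkeeping", {
  set.seed(4)
  n <- 100
  good <- replicate(6, rbinom(n, 2, 0.4))
  rare <- rbinom(n, 2, 0.004)                       # MAF < 1%
  hwe_bad <- c(rep(0, 50), rep(2, 50))              # no heterozygotes
  d <- cbind(good, rare, hwe_bad)
  mask <- matrix(FALSE, n, ncol(d))
  mask[1:11, 1] <- TRUE                             # 11% missing -> removed
  mask[1:5, 2] <- TRUE                              # 5% missing -> kept
  d[mask] <- NA
  g <- make_geno(d, mask = mask)
  res <- filter_genotypes(g)
  rep <- res$report
  expect_equal(rep$n_removed_callrate, 1)
  expect_equal(rep$removed_callrate, "s01")
  expect_equal(rep$n_removed_hwe, 1)
  expect_equal(rep$removed_hwe, "s08")
  expect_equal(rep$n_removed_maf, 1)
  expect_equal(rep$removed_maf, "s07")
  expect_equal(rep$n_snps_out,
               rep$n_snps_in - rep$n_removed_callrate - rep$n_removed_hwe -
                 rep$n_removed_maf)
  # survivors are mean-imputed: no NA left, means preserved
  expect_false(anyNA(res$genotypes$dosages))
  expect_equal(res$genotypes$dosages[1, "s02"], mean(d[6:100, 2]))
})

test_that("HWE threshold is strict and skips fractional dosages", {
  # (5, 0, 5) has exact p = 0.00136: above 0.001, so retained
  expect_true(hwe_exact_test(5, 0, 5) >= 0.001 &&
                hwe_exact_test(5, 0, 5) < 0.01)
  x <- c(rep(0, 5), rep(2, 5))
  g1 <- make_geno(cbind(x, c(0, 1, 1, 2, 0, 1, 0, 1, 2, 1)))
  expect_true("s01" %in% colnames(filter_genotypes(g1)$genotypes$dosages))
  # the same configuration marked imputed (fractional) is HWE-exempt
  xf <- c(rep(0.01, 60), rep(1.99, 60))
  g2 <- make_geno(cbind(xf, rbinom(120, 2, 0.4)),
                  imputed = c(TRUE, FALSE))
  expect_true("s01" %in% colnames(filter_genotypes(g2)$genotypes$dosages))
})

make_sex_panel <- function(n = 40, swap = integer(0), constant = FALSE,
                           seed = 1) {
  set.seed(seed)
  sex <- rep(c("male", "female"), length.out = n)
  ydos <- ifelse(sex == "male", 1, 0)
  yexpr <- if (constant) rep(5, n) else
    ifelse(sex == "male", rnorm(n, 9, 0.3), rnorm(n, 5, 0.3))
  xhet <- if (constant) rep(0.5, n) else
    ifelse(sex == "male", 0, 1) * rbinom(n, 1, 0.95)
  dos <- cbind(x1 = xhet, auto = rbinom(n, 2, 0.4))
  meta <- data.frame(snp_id = c("x1", "auto"), chrom = c("X", "1"),
                     pos = c(100L, 200L), ref = "A", alt = "G",
                     maf = 0.3, imputed = FALSE, stringsAsFactors = FALSE)
  geno <- genotype_matrix(dos, meta, sprintf("S%02d", 1:n))
  pm <- data.frame(probe_id = "yprobe", gene_id = "YG1", exon_id = "e1",
                   chrom = "Y", start = 0L, end = 60L, strand = "+",
                   n_probe_snps = 0L, stringsAsFactors = FALSE)
  expr <- expression_matrix(matrix(yexpr, 1), pm, sprintf("S%02d", 1:n))
  ann <- sex
  ann[swap] <- ifelse(sex[swap] == "male", "female", "male")
  dem <- data.frame(sample_id = sprintf("S%02d", 1:n), age = 50, sex = ann,
                    ancestry = 0, population = "EUR",
                    stringsAsFactors = FALSE)
  study_panel("p", geno, expr, dem, "test")
}

test_that("sex inference separates clean clusters and finds planted swaps", {
  p <- make_sex_panel()
  res <- infer_sex(p, y_linked_probes = "yprobe", x_linked_snps = "x1")
  expect_equal(sum(res$mismatch), 0)
  p3 <- make_sex_panel(swap = c(3, 10, 21))
  res3 <- infer_sex(p3, y_linked_probes = "yprobe", x_linked_snps = "x1")
  expect_equal(which(res3$mismatch), c(3L, 10L, 21L))
})

test_that("degenerate sex features give indeterminate calls, not a crash", {
  p <- make_sex_panel(constant = TRUE)
  res <- infer_sex(p, y_linked_probes = "yprobe", x_linked_snps = "x1")
  expect_true(all(res$inferred_sex == "indeterminate"))
})

test_that("probe-SNP annotation respects coordinate and strand conventions", {
  probes <- data.frame(probe_id = c("pPlus", "pMinus"), chrom = "1",
                       start = 100L, end = 160L, strand = c("+", "-"),
                       stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = c("v101", "v160", "v161"), chrom = "1",
                         pos = c(101L, 160L, 161L), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  ann <- annotate_probe_snps(probes, variants)
  ov <- ann$overlaps
  # VCF pos 101 is the first covered base: offset 0 from the + probe's 5' end
  expect_equal(ov$offset[ov$probe_id == "pPlus" & ov$variant_id == "v101"], 0L)
  # VCF pos 160 is the last covered base: offset 0 from the - probe's 5' end
  expect_equal(ov$offset[ov$probe_id == "pMinus" & ov$variant_id == "v160"],
               0L)
  # half-open: VCF pos 161 (0-based 160) is outside [100, 160)
  expect_false("v161" %in% ov$variant_id)
  expect_equal(unname(ann$n_probe_snps), c(2L, 2L))
})

test_that("probe-SNP counts equal the brute-force overlap oracle", {
  set.seed(21)
  probes <- data.frame(probe_id = sprintf("p%04d", 1:1000),
                       chrom = sample(c("1", "2"), 1000, TRUE),
                       start = sample.int(100000, 1000),
                       strand = sample(c("+", "-"), 1000, TRUE),
                       stringsAsFactors = FALSE)
  probes$end <- probes$start + 60L
  variants <- data.frame(variant_id = sprintf("v%04d", 1:1000),
                         chrom = sample(c("1", "2"), 1000, TRUE),
                         pos = sample.int(100000, 1000), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  ann <- annotate_probe_snps(probes, variants)
  brute <- sapply(seq_len(nrow(probes)), function(i)
    sum(variants$chrom == probes$chrom[i] &
          variants$pos - 1 >= probes$start[i] &
          variants$pos - 1 < probes$end[i]))
  expect_equal(unname(ann$n_probe_snps), brute)
  # symmetric to input order
  ann2 <- annotate_probe_snps(probes[sample(1000), ], variants[sample(1000), ])
  expect_equal(ann2$n_probe_snps[names(ann$n_probe_snps)], ann$n_probe_snps)
})

corr_probes <- function(R, n = 200, seed = 1) {
  # generate probes with target correlation structure R via Cholesky
  set.seed(seed)
  k <- nrow(R)
  vals <- t(chol(R)) %*% matrix(rnorm(k * n), k, n)
  pm <- data.frame(probe_id = sprintf("pr%d", 1:k), gene_id = "G1",
                   exon_id = "e1", chrom = "1", start = 0L, end = 60L,
                   strand = "+", n_probe_snps = 0L, stringsAsFactors = FALSE)
  expression_matrix(vals, pm, sprintf("S%03d", 1:n))
}

test_that("probe clustering cuts at the 0.5 correlation distance", {
  R_hi <- matrix(c(1, 0.9, 0.9, 1), 2)
  ps <- cluster_probes_to_probesets(corr_probes(R_hi, n = 2000))
  expect_equal(length(unique(ps$map$probeset_id)), 1)
  R_lo <- matrix(c(1, 0.3, 0.3, 1), 2)
  ps2 <- cluster_probes_to_probesets(corr_probes(R_lo, n = 2000))
  expect_equal(length(unique(ps2$map$probeset_id)), 2)
  # probeset expression is the member mean
  e <- corr_probes(R_hi, n = 50, seed = 3)
  ps3 <- cluster_probes_to_probesets(e)
  expect_equal(as.vector(ps3$expr$values[1, ]),
               as.vector(colMeans(e$values)))
})

test_that("probe clustering matches the exhaustive complete-linkage oracle", {
  set.seed(31)
  for (rep in 1:20) {
    k <- 5
    A <- matrix(rnorm(k * k), k)
    R <- stats::cov2cor(crossprod(A) + diag(k) * 0.1)
    e <- corr_probes(R, n = 300, seed = rep)
    ps <- cluster_probes_to_probesets(e)
    d <- 1 - stats::cor(t(e$values))
    oracle <- complete_linkage_oracle(d, 0.5)
    got <- as.integer(factor(ps$map$probeset_id[match(
      e$probe_meta$probe_id, ps$map$probe_id)]))
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(table(got, oracle) %in%
                      c(0, table(oracle))))
    expect_true(all(ps$min_internal_cor >= 0.5 - 1e-12))
  }
})

test_that("Dixon screen flags gross outliers and is calibrated per tail", {
  expect_equal(dixon_outlier_flag(c(1, 1.1, 0.9, 1.05, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(dixon_outlier_flag(rep(2, 10)), rep(FALSE, 10))
  expect_equal(dixon_outlier_flag(c(1, 2, 3)), rep(FALSE, 3))  # n < 4
  set.seed(8)
  hits_high <- 0
  nsim <- 4000
  for (i in seq_len(nsim)) {
    x <- rnorm(10)
    f <- dixon_outlier_flag(x)
    if (f[which.max(x)]) hits_high <- hits_high + 1
  }
  rate <- hits_high / nsim
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / nsim))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nsim))
})

test_that("TSS distances are signed by transcriptional orientation", {
  expect_equal(tss_distance(900, 1000, "+"), -100)
  expect_equal(tss_distance(900, 1000, "-"), 100)
  expect_equal(tss_distance(1000, 1000, "+"), 0)
  expect_error(tss_distance(900, 1000, "+", snp_chrom = "1",
                            gene_chrom = "2"), "same chromosome")
})
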