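#' Genotype dosage matrix
#'
#' Container for a samples x SNPs matrix of allele dosages in `[0, 2]`
#' (hard calls or mean-imputed fractional dosages) plus per-SNP metadata.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns.
#' @param snp_meta data.frame with one row per SNP and columns `snp_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `maf`, `imputed`.
#' @param sample_ids character vector of row identifiers.
#' @param mask optional logical matrix marking originally missing calls
#'   (same shape as `dosages`); dosages under the mask may be `NA` until
#'   QC mean-imputes them.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids = rownames(dosages),
                            mask = NULL) {
  dosages <- as.matrix(dosages)
  assert_that(ncol(dosages) == nrow(snp_meta),
              "snp_meta rows (%d) must match dosage columns (%d)",
              nrow(snp_meta), ncol(dosages))
  assert_that(!is.null(sample_ids) && length(sample_ids) == nrow(dosages),
              "sample_ids must name every dosage row")
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "maf", "imputed")
  assert_that(all(need %in% names(snp_meta)),
              "snp_meta must contain columns: %s", paste(need, collapse = ", "))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$snp_id
  # positions strictly increasing within chromosome
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    assert_that(all(diff(p) > 0),
                "SNP positions must be strictly increasing within chromosome %s", ch)
  }
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 sample_ids = sample_ids, mask = mask),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%d imputed)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$snp_meta$imputed)))
  invisible(x)
}

#' Expression matrix
#'
#' Probes x columns matrix of log2 intensities. Columns are samples, or
#' technical replicates of samples when `replicate_ids` is given (then
#' `sample_ids` maps each column to its sample).
#'
#' @param values numeric matrix, probes in rows.
#' @param probe_meta data.frame with columns `probe_id`, `gene_id`, `exon_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `n_probe_snps`.
#' @param sample_ids sample identifier for every column.
#' @param replicate_ids optional per-column replicate labels.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_meta, sample_ids,
                              replicate_ids = NULL) {
  values <- as.matrix(values)
  assert_that(nrow(values) == nrow(probe_meta),
              "probe_meta rows must match value rows")
  assert_that(length(sample_ids) == ncol(values),
              "sample_ids must label every column")
  assert_that(all(is.finite(values)), "expression values must be finite")
  assert_that(anyDuplicated(probe_meta$probe_id) == 0, "duplicate probe ids")
  rownames(values) <- probe_meta$probe_id
  colnames(values) <- if (is.null(replicate_ids)) sample_ids else
    paste(sample_ids, replicate_ids, sep = "_")
  structure(list(values = values, probe_meta = probe_meta,
                 sample_ids = sample_ids, replicate_ids = replicate_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d columns (%d samples)\n",
              nrow(x$values), ncol(x$values), length(unique(x$sample_ids))))
  invisible(x)
}

#' Study panel
#'
#' One cohort: genotypes, expression, demographics and a platform label.
#' The unit of eQTL discovery and replication.
#'
#' @param name panel name.
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()].
#' @param demographics data.frame with columns `sample_id`, `age`, `sex`
#'   (`"male"`/`"female"`), one or more `ancestry*` columns and `population`.
#' @param platform platform label.
#'
#' @return An object of class `study_panel`.
#' @export
study_panel <- function(name, genotypes, expression, demographics, platform) {
  assert_that(all(c("sample_id", "age", "sex", "population") %in%
                    names(demographics)),
              "demographics needs sample_id, age, sex, population")
  assert_that(all(demographics$age >= 0), "ages must be non-negative")
  assert_that(setequal(genotypes$sample_ids, demographics$sample_id),
              "genotype and demographic sample ids disagree in panel %s", name)
  assert_that(all(expression$sample_ids %in% genotypes$sample_ids),
              "expression columns reference unknown samples in panel %s", name)
  structure(list(name = name, genotypes = genotypes, expression = expression,
                 demographics = demographics, platform = platform),
            class = "study_panel")
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf("<study_panel> %s [%s]: %d samples, %d SNPs, %d probes\n",
              x$name, x$platform, length(x$genotypes$sample_ids),
              ncol(x$genotypes$dosages), nrow(x$expression$values)))
  invisible(x)
}
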