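# Readers and writers for the standard on-disk formats: genotype matrices
# (TSV or VCF with per-sample dosages), expression matrices (TSV with
# sample_replicate column headers), demographics (TSV), probe annotation
# (BED6+), gene models (BED or GTF) and reporter plates (TSV).

#' Read a genotype matrix
#'
#' TSV format: columns `snp_id`, `chrom`, `pos`, `ref`, `alt`, `imputed`,
#' then one column per sample holding dosages (empty/NA = missing). VCF: one
#' record per SNP; dosages come from the per-sample `DS` field when present,
#' otherwise from `GT` allele counts; mixed ploidy is rejected.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()] (with a missingness `mask` if any calls are
#'   missing); `maf` is recomputed from the observed dosages.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    fixed <- c("snp_id", "chrom", "pos", "ref", "alt", "imputed")
    assert_that(all(fixed %in% names(d)),
                "genotype TSV must start with columns: %s",
                paste(fixed, collapse = ", "))
    samples <- setdiff(names(d), fixed)
    dos <- t(as.matrix(d[, samples, drop = FALSE]))
    storage.mode(dos) <- "double"
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- v@fix                      # CHROM POS ID REF ALT QUAL FILTER INFO
    ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                   error = function(e) NULL)
    if (is.null(ds) || all(is.na(ds))) {
      gt <- vcfR::extract.gt(v, element = "GT")
      ploidy <- nchar(gsub("[^0-9.]", "", gt))
      assert_that(length(unique(stats::na.omit(ploidy[gt != "."]))) <= 1,
                  "mixed ploidy in VCF")
      ds <- vapply(seq_len(ncol(gt)), function(j)
        vapply(gt[, j], function(x) {
          if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
          sum(as.numeric(strsplit(x, "[/|]")[[1]]))
        }, numeric(1)), numeric(nrow(gt)))
      ds <- matrix(ds, nrow = nrow(gt),
                   dimnames = list(rownames(gt), colnames(gt)))
    }
    dos <- t(ds)
    d <- data.frame(snp_id = fx[, "ID"], chrom = fx[, "CHROM"],
                    pos = as.integer(fx[, "POS"]), ref = fx[, "REF"],
                    alt = fx[, "ALT"],
                    imputed = grepl("IMPUTED",
                                    ifelse(is.na(fx[, "INFO"]), "",
                                           fx[, "INFO"])),
                    stringsAsFactors = FALSE)
  }
  mask <- is.na(dos)
  fhat <- colMeans(dos, na.rm = TRUE) / 2
  meta <- data.frame(snp_id = d$snp_id, chrom = as.character(d$chrom),
                     pos = as.integer(d$pos), ref = d$ref, alt = d$alt,
                     maf = pmin(fhat, 1 - fhat),
                     imputed = as.logical(d$imputed),
                     stringsAsFactors = FALSE)
  o <- order(meta$chrom, meta$pos)
  genotype_matrix(dos[, o, drop = FALSE], meta[o, , drop = FALSE],
                  sample_ids = rownames(dos),
                  mask = if (any(mask)) mask[, o, drop = FALSE] else NULL)
}

#' Write a genotype matrix as TSV
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(g, path) {
  d <- cbind(g$snp_meta[, c("snp_id", "chrom", "pos", "ref", "alt",
                            "imputed")],
             as.data.frame(t(g$dosages), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with probe metadata columns (`probe_id`, `gene_id`, `exon_id`,
#' `chrom`, `start`, `end`, `strand`, `n_probe_snps`) followed by one column
#' per measurement. Replicate columns are named `sample_rK` (e.g.
#' `S001_r1`, `S001_r2`) and are mapped back to their samples.
#'
#' @param path input file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("probe_id", "gene_id", "exon_id", "chrom", "start", "end",
             "strand", "n_probe_snps")
  assert_that(all(fixed %in% names(d)),
              "expression TSV must start with columns: %s",
              paste(fixed, collapse = ", "))
  cols <- setdiff(names(d), fixed)
  vals <- as.matrix(d[, cols, drop = FALSE])
  rep_match <- regmatches(cols, regexec("^(.*)_(r[0-9]+)$", cols))
  has_rep <- vapply(rep_match, length, 1L) == 3
  if (all(has_rep)) {
    sample_ids <- vapply(rep_match, `[`, "", 2)
    replicate_ids <- vapply(rep_match, `[`, "", 3)
  } else {
    sample_ids <- cols
    replicate_ids <- NULL
  }
  expression_matrix(vals, d[, fixed], sample_ids = sample_ids,
                    replicate_ids = replicate_ids)
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  d <- cbind(expr$probe_meta[, c("probe_id", "gene_id", "exon_id", "chrom",
                                 "start", "end", "strand", "n_probe_snps")],
             as.data.frame(expr$values, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read demographics TSV
#' @param path input file with columns `sample_id`, `age`, `sex`, ancestry
#'   column(s) and `population`.
#' @return data.frame.
#' @export
read_demographics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("sample_id", "age", "sex", "population") %in% names(d)),
              "demographics TSV needs sample_id, age, sex, population")
  assert_that(anyDuplicated(d$sample_id) == 0, "duplicate sample ids")
  assert_that(all(d$age >= 0), "negative ages")
  d
}

#' Write demographics TSV
#' @param dem demographics data.frame.
#' @param path output file.
#' @export
write_demographics <- function(dem, path) {
  utils::write.table(dem, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe or gene intervals from BED
#'
#' BED is 0-based half-open and passes through unchanged. Extra columns
#' beyond BED6 are kept by name when a header-bearing "BED6+" file is given.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (+ any extra columns).
#' @export
read_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,   # back to 0-based
             end = GenomicRanges::end(g),
             name = g$name %||% NA_character_,
             score = as.numeric(g$score %||% NA),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6 (+ optional extra columns)
#' @param d data.frame with `chrom`, `start` (0-based), `end`, `name`,
#'   optional `score`, `strand`, and any extra columns.
#' @param path output file.
#' @param extra_cols names of additional columns appended after the BED6
#'   fields.
#' @export
write_bed <- function(d, path, extra_cols = character(0)) {
  out <- data.frame(d$chrom, d$start, d$end,
                    d$name %||% ".", d$score %||% 0,
                    d$strand %||% ".")
  for (ec in extra_cols) out[[ec]] <- d[[ec]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF/GFF or BED
#'
#' Genes are reduced to `(gene_id, chrom, tss, strand)`: the TSS is the
#' interval start for + strand features and the interval end for - strand
#' features (1-based).
#'
#' @param path GTF/GFF (uses `gene` features, or all features if none) or
#'   BED file.
#' @param format `"gtf"` or `"bed"` (guessed from the extension by default).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_models <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.bed$", path, ignore.case = TRUE))
    "bed" else "gtf"
  if (format == "bed") {
    b <- read_bed(path)
    assert_that(anyDuplicated(b$name) == 0, "duplicate gene ids in BED")
    return(data.frame(gene_id = b$name, chrom = b$chrom,
                      tss = ifelse(b$strand == "-", b$end, b$start + 1L),
                      strand = b$strand, stringsAsFactors = FALSE))
  }
  g <- rtracklayer::import(path, format = "GTF")
  if (any(g$type == "gene")) g <- g[g$type == "gene"]
  ids <- g$gene_id %||% g$ID %||% g$Name
  assert_that(!is.null(ids) && anyDuplicated(ids) == 0,
              "GTF must carry unique gene_id attributes")
  strand <- as.character(GenomicRanges::strand(g))
  data.frame(gene_id = ids, chrom = as.character(GenomicRanges::seqnames(g)),
             tss = ifelse(strand == "-", GenomicRanges::end(g),
                          GenomicRanges::start(g)),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a reporter plate TSV
#' @param path TSV with columns `region_id`, `haplotype_id`, `prep_id`,
#'   `replicate_index`, `luminescence`.
#' @return `reporter_plate` data.frame.
#' @export
read_reporter_plate <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "haplotype_id", "prep_id", "replicate_index",
            "luminescence")
  assert_that(all(need %in% names(d)), "reporter TSV needs columns: %s",
              paste(need, collapse = ", "))
  class(d) <- c("reporter_plate", "data.frame")
  d
}

#' Write a full simulated panel to a directory
#'
#' Writes `genotypes.tsv`, `expression.tsv`, `demographics.tsv` and
#' `probes.bed` under `dir`.
#'
#' @param panel a [study_panel()].
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(panel$genotypes, file.path(dir, "genotypes.tsv"))
  write_expression(panel$expression, file.path(dir, "expression.tsv"))
  write_demographics(panel$demographics, file.path(dir, "demographics.tsv"))
  pm <- panel$expression$probe_meta
  write_bed(data.frame(chrom = pm$chrom, start = pm$start, end = pm$end,
                       name = pm$probe_id, score = 0, strand = pm$strand,
                       gene_id = pm$gene_id, exon_id = pm$exon_id),
            file.path(dir, "probes.bed"),
            extra_cols = c("gene_id", "exon_id"))
  invisible(dir)
}
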