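AUTOSOMES <- as.character(1:22)

#' Read genotypes from VCF or PLINK traw
#'
#' Reads bi-allelic genotypes and re-orients dosages so that they count the
#' minor allele as observed in the sample (frequency ties keep the file's
#' ALT / COUNTED allele). Missing calls (`./.` or `NA`) become `NA`.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` (VCF v4.2, GT field only) or `"traw"` (PLINK
#'   transposed-text dosage).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "traw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_traw(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  if (any(n_alt != 1L)) {
    bad <- rownames(vcf)[n_alt != 1L]
    stop("multi-allelic records not supported: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alt_list))
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    snp_id = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    minor_allele = alt,
    indel = nchar(ref) > 1L | nchar(alt) > 1L,
    stringsAsFactors = FALSE)
  # GT strings -> ALT allele count; tolerate phased separators
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  vals <- map[gt]
  unknown <- is.na(vals) & !(gt %in% c("./.", ".", ".|."))
  if (any(unknown)) {
    stop("unparseable GT value(s): ",
         paste(utils::head(unique(gt[unknown]), 5), collapse = ", "))
  }
  d <- t(matrix(vals, nrow = nrow(gt)))
  gm <- genotype_matrix(d, colnames(gt), snps)
  orient_to_minor(gm)
}

read_genotypes_traw <- function(path) {
  tr <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  if (!all(fixed %in% names(tr))) {
    stop("malformed traw header: expected columns ",
         paste(fixed, collapse = ", "))
  }
  if (any(grepl(",", tr$ALT, fixed = TRUE))) {
    stop("multi-allelic records not supported: ",
         paste(utils::head(tr$SNP[grepl(",", tr$ALT, fixed = TRUE)], 5),
               collapse = ", "))
  }
  sample_cols <- setdiff(names(tr), fixed)
  if (!length(sample_cols)) stop("traw file has no sample columns")
  d <- t(as.matrix(tr[, sample_cols, drop = FALSE]))
  # traw counts the COUNTED allele; treat it as the provisional alt allele
  snps <- data.frame(
    snp_id = tr$SNP, chrom = as.character(tr$CHR), pos = tr$POS,
    ref = tr$ALT, alt = tr$COUNTED,
    minor_allele = tr$COUNTED,
    indel = nchar(tr$ALT) > 1L | nchar(tr$COUNTED) > 1L,
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(d, sample_cols, snps)
  orient_to_minor(gm)
}

# Flip any SNP whose counted-allele frequency exceeds 0.5 in the sample, so
# dosage always counts the minor allele. Exact ties keep the alt allele.
orient_to_minor <- function(gm) {
  f <- colMeans(gm$dosage, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  flip <- which(f > 0.5)
  if (length(flip)) {
    gm$dosage[, flip] <- 2L - gm$dosage[, flip]
    gm$snps$minor_allele[flip] <- gm$snps$ref[flip]
  }
  gm
}

#' Apply SNP-level quality-control filters
#'
#' Filters SNPs by, in fixed fate order: non-autosomal contig, indel,
#' call rate, minor allele frequency, and exact-test Hardy-Weinberg
#' disequilibrium. Each excluded SNP is assigned exactly one fate, the first
#' filter it fails, so the report counts sum to the input count.
#'
#' @param gm A [genotype_matrix()].
#' @param call_rate_min Minimum per-SNP call rate (default 0.99).
#' @param maf_min Minimum minor allele frequency over non-missing calls
#'   (default 0.01).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-5).
#' @return A list with `genotypes` (the retained [genotype_matrix()],
#'   participant order preserved) and `report` (a `qc_report`).
#' @export
apply_qc <- function(gm, call_rate_min = 0.99, maf_min = 0.01,
                     hwe_p_min = 1e-5) {
  if (!inherits(gm, "genotype_matrix")) stop("gm must be a genotype_matrix")
  if (nrow(gm$snps) == 0L) stop("genotype matrix has no SNPs")
  thr <- c(call_rate_min, maf_min, hwe_p_min)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1)) {
    stop("QC thresholds must lie in [0, 1]")
  }
  fate <- rep("retained", nrow(gm$snps))
  fate[snp_hwe_p(gm) < hwe_p_min] <- "hwe"
  fate[snp_maf(gm) < maf_min] <- "maf"
  fate[snp_call_rate(gm) < call_rate_min] <- "call_rate"
  fate[gm$snps$indel] <- "indel"
  fate[!(gm$snps$chrom %in% AUTOSOMES)] <- "non_autosomal"

  keep <- fate == "retained"
  report <- structure(
    list(n_input = length(fate),
         n_excluded_call_rate = sum(fate == "call_rate"),
         n_excluded_maf = sum(fate == "maf"),
         n_excluded_hwe = sum(fate == "hwe"),
         n_excluded_indel = sum(fate == "indel"),
         n_excluded_nonautosomal = sum(fate == "non_autosomal"),
         n_retained = sum(keep),
         fates = data.frame(snp_id = gm$snps$snp_id, fate = fate,
                            stringsAsFactors = FALSE)),
    class = "qc_report")
  list(genotypes = subset_snps(gm, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_report> %d SNPs in, %d retained\n",
    "  excluded: non-autosomal %d, indel %d, call rate %d, MAF %d, HWE %d\n"),
    x$n_input, x$n_retained, x$n_excluded_nonautosomal, x$n_excluded_indel,
    x$n_excluded_call_rate, x$n_excluded_maf, x$n_excluded_hwe))
  invisible(x)
}

#' Write a QC report to disk
#'
#' Emits the per-SNP fate table as TSV and the exclusion counts as JSON.
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fate_path <- file.path(dir, "qc_fates.tsv")
  json_path <- file.path(dir, "qc_summary.json")
  utils::write.table(report$fates, fate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report[setdiff(names(report), "fates")], json_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fate_path, json_path))
}
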