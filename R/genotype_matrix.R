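#' Construct a genotype matrix
#'
#' The central genotype container: a participants x SNPs dosage matrix in
#' {0, 1, 2, NA} counting minor alleles, plus per-SNP metadata.
#'
#' @param dosage Integer matrix, participants in rows, SNPs in columns,
#'   values in 0/1/2 or NA for missing calls.
#' @param participant_ids Character vector, one per row of `dosage`.
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `minor_allele`, `indel`; one row per column of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, participant_ids, snps) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(participant_ids)) {
    stop("dosage rows must match participant_ids")
  }
  if (ncol(dosage) != nrow(snps)) stop("dosage columns must match snps rows")
  needed <- c("snp_id", "chrom", "pos", "ref", "alt", "minor_allele", "indel")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols)) {
    stop("snps is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(snps$ref)) || any(!nzchar(snps$alt))) {
    stop("alleles must be non-empty")
  }
  bad <- !(dosage %in% c(0, 1, 2, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  rownames(dosage) <- participant_ids
  colnames(dosage) <- snps$snp_id
  structure(
    list(participant_ids = as.character(participant_ids),
         snps = as.data.frame(snps, stringsAsFactors = FALSE),
         dosage = dosage),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d participants x %d SNPs\n",
              length(x$participant_ids), nrow(x$snps)))
  cr <- mean(!is.na(x$dosage))
  cat(sprintf("  overall call rate: %.4f\n", cr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by SNP
#'
#' @param gm A [genotype_matrix()].
#' @param idx Integer or logical index over SNPs.
#' @return A `genotype_matrix` restricted to the selected SNPs.
#' @export
subset_snps <- function(gm, idx) {
  genotype_matrix(gm$dosage[, idx, drop = FALSE], gm$participant_ids,
                  gm$snps[idx, , drop = FALSE])
}

#' Per-SNP call rate
#'
#' Fraction of non-missing calls per SNP.
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector.
#' @export
snp_call_rate <- function(gm) colMeans(!is.na(gm$dosage))

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls only, and folded so the value is always
#' the frequency of the rarer allele (<= 0.5).
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector.
#' @export
snp_maf <- function(gm) {
  f <- colMeans(gm$dosage, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}

#' Per-SNP genotype counts
#'
#' @param gm A [genotype_matrix()].
#' @return Matrix with columns `n0`, `n1`, `n2`: counts of dosage 0/1/2.
#' @export
genotype_counts <- function(gm) {
  cbind(n0 = colSums(gm$dosage == 0, na.rm = TRUE),
        n1 = colSums(gm$dosage == 1, na.rm = TRUE),
        n2 = colSums(gm$dosage == 2, na.rm = TRUE))
}

#' Per-SNP exact HWE p-values
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of [hwe_exact_test()] p-values. SNPs with no
#'   calls at all return NA.
#' @export
snp_hwe_p <- function(gm) {
  cnt <- genotype_counts(gm)
  p <- rep(NA_real_, nrow(cnt))
  tot <- rowSums(cnt)
  ok <- tot >= 1
  p[ok] <- vapply(which(ok), function(i) {
    hwe_exact_test(cnt[i, 1L], cnt[i, 2L], cnt[i, 3L])
  }, numeric(1))
  names(p) <- gm$snps$snp_id
  p
}
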