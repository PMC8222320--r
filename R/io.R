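# Plain-text writers and readers for the pipeline's exchange formats.
# Genotype writers emit dosage as the count of the file's ALT / COUNTED
# allele; if a SNP was re-oriented on reading (minor == ref) the dosage is
# flipped back so a write/read round trip is lossless.

#' Write genotypes as VCF v4.2
#'
#' GT-only, one ALT allele per record, autosomes declared as contigs 1..22
#' plus any other contig present.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  d <- alt_oriented_dosage(gm)
  contigs <- unique(c(AUTOSOMES, gm$snps$chrom))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=grslife",
           sprintf("##contig=<ID=%s>", contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$participant_ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(gm$snps)), function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(gm$snps$chrom[j], gm$snps$pos[j], gm$snps$snp_id[j],
            gm$snps$ref[j], gm$snps$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write genotypes as PLINK transposed text (.traw)
#'
#' @inheritParams write_vcf
#' @return Invisibly, `path`.
#' @export
write_traw <- function(gm, path) {
  d <- alt_oriented_dosage(gm)
  tab <- data.frame(CHR = gm$snps$chrom, SNP = gm$snps$snp_id,
                    CM = 0, POS = gm$snps$pos,
                    COUNTED = gm$snps$alt, ALT = gm$snps$ref,
                    t(d), check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[3] <- "(C)M"
  names(tab)[-(1:6)] <- gm$participant_ids
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

alt_oriented_dosage <- function(gm) {
  d <- gm$dosage
  flip <- which(gm$snps$minor_allele == gm$snps$ref)
  if (length(flip)) d[, flip] <- 2L - d[, flip]
  d
}

#' Read a daily diet diary CSV
#'
#' Schema: `participant_id,date,meal,carb_g,fat_g,protein_g,kcal`.
#' @param path CSV path.
#' @return `data.frame` with `date` parsed as `Date`.
#' @export
read_diet_diary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "meal", "carb_g", "fat_g",
            "protein_g", "kcal")
  check_schema(df, need, path)
  df$date <- as.Date(df$date)
  if (any(df$carb_g < 0 | df$fat_g < 0 | df$protein_g < 0, na.rm = TRUE)) {
    stop("negative nutrient grams in ", path)
  }
  df
}

#' Read a daily activity diary CSV
#'
#' Schema: `participant_id,date,kcal_expended,minutes,intensity_frac`.
#' @param path CSV path.
#' @return `data.frame` with `date` parsed as `Date`.
#' @export
read_activity_diary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "kcal_expended", "minutes",
            "intensity_frac")
  check_schema(df, need, path)
  df$date <- as.Date(df$date)
  if (any(df$kcal_expended < 0 | df$minutes < 0, na.rm = TRUE)) {
    stop("negative activity values in ", path)
  }
  if (any(df$intensity_frac < 0 | df$intensity_frac > 1.5, na.rm = TRUE)) {
    stop("intensity_frac outside [0, 1.5] in ", path)
  }
  df
}

#' Read a phenotype table CSV
#'
#' Expects per-participant sex, age, modification group and paired
#' `*_pre`/`*_post` anthropometric and serologic columns.
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant_id", "sex", "age", "group"), path)
  df
}

check_schema <- function(df, need, path) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

#' Write a synthetic cohort to a directory of exchange files
#'
#' Emits exactly the formats the pipeline readers consume: genotypes as VCF
#' or traw, plus `phenotypes.csv`, `diet.csv` and `activity.csv`.
#'
#' @param cohort A [synthesize_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param genotype_format `"vcf"` or `"traw"`.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("vcf", "traw")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_path <- file.path(dir, paste0("genotypes.", genotype_format))
  if (genotype_format == "vcf") write_vcf(cohort$genotypes, geno_path)
  else write_traw(cohort$genotypes, geno_path)
  paths <- c(genotypes = geno_path,
             phenotypes = file.path(dir, "phenotypes.csv"),
             diet = file.path(dir, "diet.csv"),
             activity = file.path(dir, "activity.csv"))
  utils::write.csv(cohort$phenotypes, paths["phenotypes"], row.names = FALSE)
  utils::write.csv(cohort$diet, paths["diet"], row.names = FALSE)
  utils::write.csv(cohort$activity, paths["activity"], row.names = FALSE)
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
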