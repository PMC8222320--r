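# Genetic risk scores: coefficient-weighted minor-allele counts.
# GRS = sum_i weight_i * dosage_i over the panel SNPs. Dosages keep the
# minor-allele orientation used at fitting time and weights keep their
# sign, so the score is exactly the fitted interaction linear predictor
# per unit of lifestyle change.

#' Score participants against one GRS panel
#'
#' @param gm A [genotype_matrix()].
#' @param panel `data.frame` with `snp_id` and `weight` (one element of a
#'   `grs_panels` object).
#' @param missing_policy How to handle missing dosages: `"mean_impute"`
#'   (default; a missing call contributes the SNP's sample mean dosage, so
#'   every participant gets a score) or `"drop_snp"` (a missing call
#'   contributes 0 for that participant).
#' @return `data.frame`: `participant_id`, `score`. An empty panel scores 0
#'   for everyone.
#' @export
grs_score <- function(gm, panel, missing_policy = c("mean_impute",
                                                    "drop_snp")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(panel) == 0) {
    return(data.frame(participant_id = gm$participant_ids, score = 0,
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(panel$snp_id)) stop("panel snp_ids must be unique")
  j <- match(panel$snp_id, gm$snps$snp_id)
  if (any(is.na(j))) {
    stop("panel SNP(s) absent from genotypes: ",
         paste(panel$snp_id[is.na(j)], collapse = ", "))
  }
  d <- gm$dosage[, j, drop = FALSE]
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      mu <- colMeans(d, na.rm = TRUE)
      mu[is.nan(mu)] <- 0          # SNP with no calls at all contributes 0
      na_idx <- which(is.na(d), arr.ind = TRUE)
      d[na_idx] <- mu[na_idx[, 2]]
    } else {
      d[is.na(d)] <- 0
    }
  }
  data.frame(participant_id = gm$participant_ids,
             score = as.numeric(d %*% panel$weight),
             stringsAsFactors = FALSE)
}

#' Compute GRS-C, GRS-F and GRS-E for every participant
#'
#' @param gm A [genotype_matrix()].
#' @param panels A `grs_panels` object from [build_panels()].
#' @inheritParams grs_score
#' @return `data.frame`: `participant_id`, `grs_c`, `grs_f`, `grs_e`.
#' @export
grs_score_all <- function(gm, panels, missing_policy = c("mean_impute",
                                                         "drop_snp")) {
  missing_policy <- match.arg(missing_policy)
  data.frame(participant_id = gm$participant_ids,
             grs_c = grs_score(gm, panels$C, missing_policy)$score,
             grs_f = grs_score(gm, panels$F, missing_policy)$score,
             grs_e = grs_score(gm, panels$E, missing_policy)$score,
             stringsAsFactors = FALSE)
}
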