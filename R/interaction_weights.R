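# Per-SNP gene-environment interaction regression. Two model families:
#   diet:     dBFM ~ gender + age + age^2 + G + dC + dF + G:dC + G:dF
#   exercise: dBFM ~ gender + age + age^2 + G + dE + G:dE
# with G the minor-allele dosage. The fitted interaction coefficients are
# the GRS weights.

#' Build the covariate table for interaction fitting
#'
#' Joins phenotypes and lifestyle deltas into the regression frame:
#' gender, age, age squared, the three deltas, and the body-fat-mass change
#' (post minus pre, kg).
#'
#' @param phenotypes Phenotype `data.frame` with `participant_id`, `sex`,
#'   `age`, `bfm_pre`, `bfm_post`.
#' @param deltas Output of [compute_lifestyle_delta()]; rows with
#'   `included = FALSE` are dropped.
#' @return `data.frame` of covariate rows.
#' @export
covariate_rows <- function(phenotypes, deltas) {
  use <- deltas[deltas$included, , drop = FALSE]
  i <- match(use$participant_id, phenotypes$participant_id)
  if (any(is.na(i))) {
    stop("deltas contain participants absent from the phenotype table")
  }
  data.frame(participant_id = use$participant_id,
             gender = phenotypes$sex[i],
             age = phenotypes$age[i],
             age_sq = phenotypes$age[i]^2,
             delta_c = use$delta_c, delta_f = use$delta_f,
             delta_e = use$delta_e,
             delta_bfm = phenotypes$bfm_post[i] - phenotypes$bfm_pre[i],
             group = phenotypes$group[i],
             stringsAsFactors = FALSE)
}

#' Fit the diet interaction model for one SNP
#'
#' Ordinary least squares of the BFM change on intercept, gender, age,
#' age squared, dosage, delta-carbohydrate, delta-fat and the two
#' dosage-by-delta interactions. Complete-case: rows with a missing dosage
#' or delta are dropped.
#'
#' @param dosage Numeric vector of minor-allele dosages aligned with
#'   `covariates` rows (NA = missing call).
#' @param covariates Output of [covariate_rows()].
#' @param snp_id Identifier carried into the result.
#' @param robust Report heteroskedasticity-robust (HC1 sandwich) standard
#'   errors and p-values for the interaction terms (default TRUE). In a
#'   polygenic world each per-SNP regression leaves the other SNPs'
#'   interaction signal in its residual, which is heteroskedastic in the
#'   lifestyle delta; classical OLS standard errors are then
#'   anticonservative. Set FALSE for classical errors.
#' @return One-row `data.frame` with the carbohydrate and fat interaction
#'   coefficients (`beta_c`, `beta_f`), their standard errors and two-sided
#'   p-values, `n_used`, and `skipped`/`reason` for degenerate designs.
#' @export
fit_diet_model <- function(dosage, covariates, snp_id = NA_character_,
                           robust = TRUE) {
  fit_interaction(dosage, covariates, snp_id, model = "diet",
                  robust = robust)
}

#' Fit the exercise interaction model for one SNP
#'
#' As [fit_diet_model()] but with regressors intercept, gender, age,
#' age squared, dosage, delta-exercise and dosage-by-delta-exercise.
#' The interaction term is dosage x delta_e: the exercise model's
#' interaction coefficient multiplies the exercise change just as the diet
#' coefficients multiply the nutrient changes.
#'
#' @inheritParams fit_diet_model
#' @return One-row `data.frame` with `beta_e`, `se_e`, `p_e`, `n_used`,
#'   `skipped`, `reason`.
#' @export
fit_exercise_model <- function(dosage, covariates, snp_id = NA_character_,
                               robust = TRUE) {
  fit_interaction(dosage, covariates, snp_id, model = "exercise",
                  robust = robust)
}

fit_interaction <- function(dosage, covariates, snp_id, model, robust) {
  if (length(dosage) != nrow(covariates)) {
    stop("dosage length must match covariate rows")
  }
  delta_cols <- if (model == "diet") c("delta_c", "delta_f") else "delta_e"
  df <- data.frame(g = as.numeric(dosage),
                   covariates[, c("gender", "age", "age_sq", delta_cols,
                                  "delta_bfm")])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stop("need >= 10 complete cases, got ", n)

  skip <- function(reason) {
    row <- data.frame(snp_id = snp_id, model = model, n_used = n,
                      skipped = TRUE, reason = reason,
                      stringsAsFactors = FALSE)
    fill_weight_cols(row, model)
  }
  if (stats::var(df$g) == 0) return(skip("constant dosage"))

  form <- if (model == "diet") {
    delta_bfm ~ gender + age + age_sq + g + delta_c + delta_f +
      g:delta_c + g:delta_f
  } else {
    delta_bfm ~ gender + age + age_sq + g + delta_e + g:delta_e
  }
  fit <- stats::lm(form, data = df)
  co <- summary(fit)$coefficients
  inter_terms <- if (model == "diet") c("g:delta_c", "g:delta_f")
                 else "g:delta_e"
  if (any(is.na(stats::coef(fit))) ||
      !all(inter_terms %in% rownames(co))) {
    return(skip("rank-deficient design"))
  }
  if (robust) {
    vc <- hc1_vcov(fit)
    se <- sqrt(diag(vc))[inter_terms]
    est <- stats::coef(fit)[inter_terms]
    pv <- 2 * stats::pt(-abs(est / se), df = fit$df.residual)
    co[inter_terms, "Std. Error"] <- se
    co[inter_terms, "Pr(>|t|)"] <- pv
  }
  row <- data.frame(snp_id = snp_id, model = model, n_used = n,
                    skipped = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (model == "diet") {
    row$beta_c <- co["g:delta_c", "Estimate"]
    row$se_c <- co["g:delta_c", "Std. Error"]
    row$p_c <- co["g:delta_c", "Pr(>|t|)"]
    row$beta_f <- co["g:delta_f", "Estimate"]
    row$se_f <- co["g:delta_f", "Std. Error"]
    row$p_f <- co["g:delta_f", "Pr(>|t|)"]
  } else {
    row$beta_e <- co["g:delta_e", "Estimate"]
    row$se_e <- co["g:delta_e", "Std. Error"]
    row$p_e <- co["g:delta_e", "Pr(>|t|)"]
  }
  row
}

# HC1 sandwich covariance (degrees-of-freedom corrected White estimator)
hc1_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  n <- nrow(X)
  k <- ncol(X)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * u)
  n / (n - k) * bread %*% meat %*% bread
}

fill_weight_cols <- function(row, model) {
  cols <- if (model == "diet") {
    c("beta_c", "se_c", "p_c", "beta_f", "se_f", "p_f")
  } else {
    c("beta_e", "se_e", "p_e")
  }
  for (cl in cols) row[[cl]] <- NA_real_
  row
}

#' Fit one interaction model family across many SNPs
#'
#' @param gm A [genotype_matrix()].
#' @param covariates Output of [covariate_rows()]; only participants
#'   present in both `gm` and `covariates` are used.
#' @param model `"diet"` or `"exercise"`.
#' @param snp_ids SNPs to fit (default: all in `gm`).
#' @inheritParams fit_diet_model
#' @return `data.frame`, one row per SNP, in the [fit_diet_model()] /
#'   [fit_exercise_model()] schema.
#' @export
fit_interaction_models <- function(gm, covariates,
                                   model = c("diet", "exercise"),
                                   snp_ids = NULL, robust = TRUE) {
  model <- match.arg(model)
  if (is.null(snp_ids)) snp_ids <- gm$snps$snp_id
  missing_snps <- setdiff(snp_ids, gm$snps$snp_id)
  if (length(missing_snps)) {
    stop("SNPs absent from genotypes: ",
         paste(utils::head(missing_snps, 5), collapse = ", "))
  }
  rows_i <- match(covariates$participant_id, gm$participant_ids)
  if (any(is.na(rows_i))) {
    stop("covariates contain participants absent from genotypes")
  }
  fit_one <- if (model == "diet") fit_diet_model else fit_exercise_model
  res <- lapply(snp_ids, function(s) {
    fit_one(gm$dosage[rows_i, s], covariates, snp_id = s, robust = robust)
  })
  as.data.frame(data.table::rbindlist(res, fill = TRUE))
}

#' Select the GRS panels from fitted interaction weights
#'
#' Picks, for each GRS type, the SNPs with the smallest interaction
#' p-values (ties broken by lexical SNP id), carrying the signed fitted
#' coefficient as the panel weight. Panel sizes default to 37 (carbohydrate),
#' 19 (fat) and 25 (exercise).
#'
#' @param diet_weights Result of `fit_interaction_models(..., "diet")`.
#' @param exercise_weights Result of
#'   `fit_interaction_models(..., "exercise")`.
#' @param panel_sizes Integer vector (C, F, E).
#' @param snp_info Optional SNP metadata (`snp_id`, `minor_allele`) used to
#'   record each entry's risk allele.
#' @return A `grs_panels` list with elements `C`, `F`, `E`, each a
#'   `data.frame` (`snp_id`, `weight`, `risk_allele`, `p_value`).
#' @export
build_panels <- function(diet_weights, exercise_weights,
                         panel_sizes = c(C = 37, F = 19, E = 25),
                         snp_info = NULL) {
  panel_sizes <- as.integer(panel_sizes)
  names(panel_sizes) <- c("C", "F", "E")
  if (any(panel_sizes < 0)) stop("panel sizes must be >= 0")
  pick <- function(w, beta_col, p_col, size, label) {
    ok <- w[!w$skipped & is.finite(w[[p_col]]), , drop = FALSE]
    if (nrow(ok) < size) {
      stop("insufficient fitted SNPs for panel ", label, ": need ", size,
           ", have ", nrow(ok))
    }
    ok <- ok[order(ok[[p_col]], ok$snp_id), , drop = FALSE]
    sel <- ok[seq_len(size), , drop = FALSE]
    risk <- if (!is.null(snp_info)) {
      snp_info$minor_allele[match(sel$snp_id, snp_info$snp_id)]
    } else rep(NA_character_, nrow(sel))
    data.frame(snp_id = sel$snp_id, weight = sel[[beta_col]],
               risk_allele = risk, p_value = sel[[p_col]],
               stringsAsFactors = FALSE)
  }
  structure(list(C = pick(diet_weights, "beta_c", "p_c", panel_sizes["C"],
                          "C"),
                 F = pick(diet_weights, "beta_f", "p_f", panel_sizes["F"],
                          "F"),
                 E = pick(exercise_weights, "beta_e", "p_e",
                          panel_sizes["E"], "E")),
            class = "grs_panels")
}

#' @export
print.grs_panels <- function(x, ...) {
  cat(sprintf("<grs_panels> C: %d SNPs, F: %d SNPs, E: %d SNPs\n",
              nrow(x$C), nrow(x$F), nrow(x$E)))
  invisible(x)
}

#' Write GRS panels as JSON
#'
#' @param panels A `grs_panels` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panels <- function(panels, path) {
  jsonlite::write_json(lapply(unclass(panels), function(p) {
    p[, c("snp_id", "weight", "risk_allele")]
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read GRS panels from JSON
#'
#' @param path JSON path written by [write_panels()].
#' @return A `grs_panels` object.
#' @export
read_panels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("C", "F", "E")
  if (!all(need %in% names(raw))) stop("panel JSON must contain C, F and E")
  structure(lapply(raw[need], function(p) {
    as.data.frame(p, stringsAsFactors = FALSE)
  }), class = "grs_panels")
}
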