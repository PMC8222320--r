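COHORT_GROUPS <- c("low_carb", "low_fat", "moderate_exercise",
                   "intense_exercise")

#' Configuration for the synthetic cohort generator
#'
#' Defaults restate the study design the pipeline targets: 259 participants
#' split over four lifestyle-modification groups in proportions 35:34:99:83,
#' aged 23-67 with 22.4% women, a 2-week baseline followed by a 12-week
#' observation period, and group mean lifestyle shifts of -24.1 g/day
#' carbohydrate (low-carb group), -16.87 g/day fat (low-fat group) and
#' +31.21 / +22.75 kcal/day exercise expenditure (intense / moderate
#' exercise groups).
#'
#' @param n_participants Cohort size.
#' @param n_snps Number of simulated bi-allelic autosomal SNPs.
#' @param panel_sizes Named or positional counts of causal SNPs for the
#'   carbohydrate, fat and exercise interaction panels (default 37, 19, 25).
#'   Panels are disjoint, so their sum must not exceed `n_snps`.
#' @param maf_range Range the per-SNP minor allele frequency is drawn from,
#'   within (0, 0.5].
#' @param missing_rate Per-call probability of a missing genotype.
#' @param group_proportions Probabilities over the four modification groups
#'   (low-carb, low-fat, moderate-exercise, intense-exercise); must sum to 1.
#' @param baseline_weeks,observation_weeks Study period lengths in weeks.
#' @param beta_c,beta_f,beta_e Planted interaction effect sizes, in kg of
#'   body fat mass per unit of lifestyle delta per minor allele, applied to
#'   every SNP of the matching panel. Defaults are chosen so the planted
#'   genetic contribution to the BFM change is of order 1 kg.
#' @param noise_sd Residual standard deviation of the BFM change, kg.
#' @param shift_sd_c,shift_sd_f,shift_sd_e Between-participant dispersion of
#'   the personal lifestyle shift within each group (g/day, g/day, kcal/day).
#' @param hom_excess Test hook: probability of converting a heterozygote to
#'   a homozygote, planting a Hardy-Weinberg violation. Default 0.
#' @param start_date First diary date (a Monday by default).
#' @param seed Integer seed; identical configurations give byte-identical
#'   cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 259, n_snps = 120,
                          panel_sizes = c(C = 37, F = 19, E = 25),
                          maf_range = c(0.05, 0.5), missing_rate = 0.002,
                          group_proportions = c(low_carb = 35, low_fat = 34,
                                                moderate_exercise = 99,
                                                intense_exercise = 83) / 251,
                          baseline_weeks = 2, observation_weeks = 12,
                          beta_c = 0.01, beta_f = 0.01, beta_e = 0.005,
                          noise_sd = 1.5,
                          shift_sd_c = 20, shift_sd_f = 12, shift_sd_e = 15,
                          hom_excess = 0, start_date = as.Date("2021-03-01"),
                          seed = 42L) {
  panel_sizes <- as.integer(panel_sizes)
  names(panel_sizes) <- c("C", "F", "E")
  counts <- c(n_participants, n_snps, baseline_weeks, observation_weeks)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (any(panel_sizes < 0)) stop("panel sizes must be >= 0")
  if (sum(panel_sizes) > n_snps) {
    stop("panel sizes exceed n_snps (panels are disjoint)")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (length(group_proportions) != 4 ||
      abs(sum(group_proportions) - 1) > 1e-9) {
    stop("group_proportions must be 4 fractions summing to 1")
  }
  names(group_proportions) <- COHORT_GROUPS
  structure(
    list(n_participants = as.integer(n_participants),
         n_snps = as.integer(n_snps), panel_sizes = panel_sizes,
         maf_range = maf_range, missing_rate = missing_rate,
         group_proportions = group_proportions,
         baseline_weeks = as.integer(baseline_weeks),
         observation_weeks = as.integer(observation_weeks),
         beta_c = beta_c, beta_f = beta_f, beta_e = beta_e,
         noise_sd = noise_sd, shift_sd_c = shift_sd_c,
         shift_sd_f = shift_sd_f, shift_sd_e = shift_sd_e,
         hom_excess = hom_excess, start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Fixed generative constants for the BFM-change linear predictor: a small
# overall drop plus weak demographic terms and nutrient/exercise main
# effects. The planted interactions come on top of these.
BFM_MODEL_CONSTANTS <- c(intercept = -0.3, sex = 0.15, age = 0.02,
                         age_sq = -2e-4, main_c = 0.01, main_f = 0.015,
                         main_e = -0.008)

#' Generate a synthetic cohort with planted gene-environment interactions
#'
#' Draws genotypes per SNP as Binomial(2, p) with p uniform in the
#' configured MAF range, simulates daily diet and activity diaries with
#' group-specific mean shifts between the baseline and observation periods,
#' and generates each participant's body-fat-mass change from the study's
#' two linear interaction models run forward: diet-group participants
#' receive carbohydrate and fat interaction signal, exercise-group
#' participants exercise interaction signal, each summed over the matching
#' causal SNP panel, plus Gaussian noise. Pre/post anthropometrics are
#' derived consistently with the generated change.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `genotypes`
#'   ([genotype_matrix()]), `phenotypes`, `diet`, `activity` (data frames in
#'   the exchange schemas) and `truth` (causal panels, planted betas, true
#'   personal lifestyle shifts and the noise-free BFM-change signal).
#' @export
synthesize_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_participants
  m <- config$n_snps
  ids <- sprintf("P%04d", seq_len(n))

  ## participants
  sex <- stats::rbinom(n, 1, 0.224)            # 1 = female
  age <- sample(23:67, n, replace = TRUE)
  group <- sample(COHORT_GROUPS, n, replace = TRUE,
                  prob = config$group_proportions)

  ## genotypes
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dose_true <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)),
                      nrow = n, ncol = m)
  if (config$hom_excess > 0) {
    het <- which(dose_true == 1L)
    conv <- het[stats::runif(length(het)) < config$hom_excess]
    dose_true[conv] <- ifelse(stats::runif(length(conv)) < 0.5, 0L, 2L)
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = as.character(sample(1:22, m, replace = TRUE)),
    pos = sort(sample.int(5e7, m)),
    ref = ref, alt = alt, minor_allele = alt,
    indel = FALSE, stringsAsFactors = FALSE)

  ## causal panels: disjoint blocks of SNP indices
  ps <- config$panel_sizes
  idx_c <- seq_len(ps["C"])
  idx_f <- seq_len(ps["F"]) + ps["C"]
  idx_e <- seq_len(ps["E"]) + ps["C"] + ps["F"]
  panels <- list(C = snps$snp_id[idx_c], F = snps$snp_id[idx_f],
                 E = snps$snp_id[idx_e])

  ## personal lifestyle shifts (the "true" deltas behind the diaries)
  shift_means <- list(
    low_carb = c(c = -24.1, f = 0, e = 0),
    low_fat = c(c = 0, f = -16.87, e = 0),
    moderate_exercise = c(c = 0, f = 0, e = 22.75),
    intense_exercise = c(c = 0, f = 0, e = 31.21))
  mu <- do.call(rbind, shift_means[group])
  d_c <- stats::rnorm(n, mu[, "c"], config$shift_sd_c)
  d_f <- stats::rnorm(n, mu[, "f"], config$shift_sd_f)
  d_e <- stats::rnorm(n, mu[, "e"], config$shift_sd_e)

  ## BFM change from the two interaction models run forward
  k <- BFM_MODEL_CONSTANTS
  base_lp <- k["intercept"] + k["sex"] * sex + k["age"] * age +
    k["age_sq"] * age^2
  inter_c <- if (length(idx_c)) rowSums(dose_true[, idx_c, drop = FALSE]) else 0
  inter_f <- if (length(idx_f)) rowSums(dose_true[, idx_f, drop = FALSE]) else 0
  inter_e <- if (length(idx_e)) rowSums(dose_true[, idx_e, drop = FALSE]) else 0
  is_diet <- group %in% c("low_carb", "low_fat")
  signal <- ifelse(
    is_diet,
    base_lp + k["main_c"] * d_c + k["main_f"] * d_f +
      config$beta_c * d_c * inter_c + config$beta_f * d_f * inter_f,
    base_lp + k["main_e"] * d_e + config$beta_e * d_e * inter_e)
  delta_bfm <- signal + stats::rnorm(n, 0, config$noise_sd)

  ## diaries
  diaries <- simulate_diaries(config, ids, d_c, d_f, d_e)

  ## phenotypes consistent with the generated change
  height <- stats::rnorm(n, ifelse(sex == 1, 1.61, 1.74), 0.06)
  bmi_pre <- pmax(stats::rnorm(n, 24.8, 3.2), 17)
  weight_pre <- bmi_pre * height^2
  bfp_pre <- pmin(pmax(stats::rnorm(n, 25.9, 6.1), 8), 45)
  bfm_pre <- weight_pre * bfp_pre / 100
  bfm_post <- bfm_pre + delta_bfm
  weight_post <- weight_pre + delta_bfm + stats::rnorm(n, 0, 0.5)
  phen <- data.frame(
    participant_id = ids, sex = sex, age = age, group = group,
    weight_pre = round(weight_pre, 2), weight_post = round(weight_post, 2),
    bfm_pre = round(bfm_pre, 3), bfm_post = round(bfm_post, 3),
    bfp_pre = round(bfp_pre, 2),
    bfp_post = round(100 * bfm_post / weight_post, 2),
    bmi_pre = round(bmi_pre, 2),
    bmi_post = round(weight_post / height^2, 2),
    smm_pre = round(pmax(stats::rnorm(n, 30.4, 6), 12), 2),
    smm_post = NA_real_,
    whr_pre = round(stats::rnorm(n, 0.87, 0.06), 3),
    whr_post = NA_real_,
    tg_pre = round(pmax(stats::rnorm(n, 128.5, 60), 30), 1),
    tg_post = NA_real_,
    ldl_pre = round(pmax(stats::rnorm(n, 125.2, 30.5), 40), 1),
    ldl_post = NA_real_,
    hdl_pre = round(pmax(stats::rnorm(n, 51.9, 13.8), 20), 1),
    hdl_post = NA_real_,
    stringsAsFactors = FALSE)
  phen$smm_post <- round(phen$smm_pre + stats::rnorm(n, 0.04, 0.74), 2)
  phen$whr_post <- round(phen$whr_pre + stats::rnorm(n, 0, 0.02), 3)
  phen$tg_post <- round(pmax(phen$tg_pre + stats::rnorm(n, 4.2, 40), 20), 1)
  phen$ldl_post <- round(pmax(phen$ldl_pre + stats::rnorm(n, -4.6, 15), 30), 1)
  phen$hdl_post <- round(pmax(phen$hdl_pre + stats::rnorm(n, -1.4, 7), 15), 1)

  ## missingness is applied after the phenotype generation so the planted
  ## signal reflects the underlying genotype, as in real data
  dose <- dose_true
  if (config$missing_rate > 0) {
    dose[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  truth_betas <- data.frame(
    snp_id = c(panels$C, panels$F, panels$E),
    panel = rep(c("C", "F", "E"), times = ps),
    beta = rep(c(config$beta_c, config$beta_f, config$beta_e), times = ps),
    stringsAsFactors = FALSE)

  structure(
    list(genotypes = genotype_matrix(dose, ids, snps),
         phenotypes = phen,
         diet = diaries$diet, activity = diaries$activity,
         truth = list(panels = panels, betas = truth_betas,
                      maf = maf,
                      deltas = data.frame(participant_id = ids, delta_c = d_c,
                                          delta_f = d_f, delta_e = d_e,
                                          stringsAsFactors = FALSE),
                      signal = signal, delta_bfm = delta_bfm,
                      model_constants = BFM_MODEL_CONSTANTS),
         config = config),
    class = "synthetic_cohort")
}

# Daily diaries: three meals a day with fixed breakfast/lunch/dinner
# proportions, and one activity record a day. Observation-period days get
# the participant's personal shift added to the daily mean.
simulate_diaries <- function(config, ids, d_c, d_f, d_e) {
  n <- length(ids)
  n_days <- 7L * (config$baseline_weeks + config$observation_weeks)
  dates <- config$start_date + seq_len(n_days) - 1L
  is_obs <- rep(seq_len(n_days) > 7L * config$baseline_weeks, times = n)

  carb_base <- stats::rnorm(n, 300, 40)
  fat_base <- stats::rnorm(n, 60, 12)
  prot_base <- stats::rnorm(n, 70, 10)
  act_base <- pmax(stats::rnorm(n, 200, 60), 30)
  minutes_base <- pmax(stats::rnorm(n, 40, 10), 10)
  intens_base <- stats::runif(n, 0.4, 0.8)

  pid <- rep(ids, each = n_days)
  day_date <- rep(dates, times = n)
  carb <- pmax(rep(carb_base, each = n_days) + is_obs * rep(d_c, each = n_days)
               + stats::rnorm(n * n_days, 0, 30), 5)
  fat <- pmax(rep(fat_base, each = n_days) + is_obs * rep(d_f, each = n_days)
              + stats::rnorm(n * n_days, 0, 12), 2)
  prot <- pmax(rep(prot_base, each = n_days) + stats::rnorm(n * n_days, 0, 10),
               5)
  meal_prop <- c(breakfast = 0.3, lunch = 0.4, dinner = 0.3)
  diet <- data.frame(
    participant_id = rep(pid, times = 3),
    date = rep(day_date, times = 3),
    meal = rep(names(meal_prop), each = n * n_days),
    carb_g = round(as.vector(outer(carb, meal_prop)), 2),
    fat_g = round(as.vector(outer(fat, meal_prop)), 2),
    protein_g = round(as.vector(outer(prot, meal_prop)), 2),
    stringsAsFactors = FALSE)
  diet$kcal <- round(4 * (diet$carb_g + diet$protein_g) + 9 * diet$fat_g, 1)
  ord <- order(diet$participant_id, diet$date, match(diet$meal,
                                                     names(meal_prop)))
  diet <- diet[ord, , drop = FALSE]
  rownames(diet) <- NULL

  kcal_exp <- pmax(rep(act_base, each = n_days) +
                     is_obs * rep(d_e, each = n_days) +
                     stats::rnorm(n * n_days, 0, 40), 0)
  activity <- data.frame(
    participant_id = pid, date = day_date,
    kcal_expended = round(kcal_exp, 1),
    minutes = round(pmax(rep(minutes_base, each = n_days) + kcal_exp / 10 - 20
                         + stats::rnorm(n * n_days, 0, 8), 0), 1),
    intensity_frac = round(pmin(pmax(rep(intens_base, each = n_days) +
                                       stats::rnorm(n * n_days, 0, 0.05), 0),
                                1.2), 3),
    stringsAsFactors = FALSE)
  list(diet = diet, activity = activity)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_cohort> %d participants, %d SNPs (panels C/F/E = %d/%d/%d)\n",
    "  diaries: %d diet rows, %d activity rows; seed %d\n"),
    length(x$genotypes$participant_ids), nrow(x$genotypes$snps),
    length(x$truth$panels$C), length(x$truth$panels$F),
    length(x$truth$panels$E), nrow(x$diet), nrow(x$activity),
    x$config$seed))
  invisible(x)
}

#' Hardy-Weinberg self-check for a synthetic cohort
#'
#' Convenience wrapper used to verify that generated genotypes are
#' HWE-consistent (or that a planted violation via `hom_excess` is
#' detected).
#'
#' @param cohort A `synthetic_cohort`.
#' @return Named vector of per-SNP exact-test p-values.
#' @export
hwe_consistency_check <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("cohort must be a synthetic_cohort")
  }
  snp_hwe_p(cohort$genotypes)
}

#' Study windows implied by a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return List with `baseline` and `observation`, each a length-2 Date
#'   vector of inclusive bounds.
#' @export
study_windows <- function(config) {
  b0 <- config$start_date
  b1 <- b0 + 7L * config$baseline_weeks - 1L
  o1 <- b1 + 7L * config$observation_weeks
  list(baseline = c(b0, b1), observation = c(b1 + 1L, o1))
}
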