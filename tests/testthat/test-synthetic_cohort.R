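test_that("identical configurations give identical cohorts", {
  c1 <- synthesize_cohort(small_config(seed = 7))
  c2 <- synthesize_cohort(small_config(seed = 7))
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$diet, c2$diet)
  expect_identical(c1$activity, c2$activity)
  expect_identical(c1$truth, c2$truth)
  c3 <- synthesize_cohort(small_config(seed = 8))
  expect_false(identical(c1$genotypes$dosage, c3$genotypes$dosage))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 0), ">= 1")
  expect_error(cohort_config(n_snps = 10, panel_sizes = c(8, 8, 8)),
               "panel sizes")
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(cohort_config(group_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "summing to 1")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})

test_that("zero missing rate gives call rate 1 for every SNP", {
  co <- synthesize_cohort(small_config(missing_rate = 0, seed = 3))
  expect_true(all(snp_call_rate(co$genotypes) == 1))
})

test_that("cohort components share participant ids and truth covers panels", {
  co <- synthesize_cohort(small_config(seed = 5))
  ids <- co$genotypes$participant_ids
  expect_setequal(co$phenotypes$participant_id, ids)
  expect_setequal(unique(co$diet$participant_id), ids)
  expect_setequal(unique(co$activity$participant_id), ids)
  panel_ids <- unlist(co$truth$panels, use.names = FALSE)
  expect_setequal(co$truth$betas$snp_id, panel_ids)
  expect_equal(length(panel_ids), sum(co$config$panel_sizes))
  # diaries span the configured study window, daily
  expect_equal(length(unique(co$diet$date)),
               7 * (co$config$baseline_weeks + co$config$observation_weeks))
})

test_that("empirical MAF stays inside the binomial 99% CI of drawn p", {
  co <- synthesize_cohort(cohort_config(n_participants = 1200, n_snps = 60,
                                        panel_sizes = c(5, 5, 5),
                                        missing_rate = 0, seed = 13,
                                        baseline_weeks = 1,
                                        observation_weeks = 1))
  n2 <- 2 * 1200
  emp <- colMeans(co$genotypes$dosage) / 2
  p <- co$truth$maf
  half <- qnorm(0.995) * sqrt(p * (1 - p) / n2)
  inside <- abs(emp - p) <= half
  # individually 99%, so allow a couple of misses out of 60
  expect_gte(sum(inside), 56)
})

test_that("null cohorts show no GRS / BFM-change association", {
  # 50 replicates, unweighted allele-count scores over each truth panel:
  # at alpha = 0.01 the 150 correlation tests should almost never reject
  n_sig <- 0L
  for (r in 1:50) {
    co <- synthesize_cohort(
      small_config(beta_c = 0, beta_f = 0, beta_e = 0, noise_sd = 1,
                   missing_rate = 0, seed = 1000 + r))
    dbfm <- co$truth$delta_bfm
    for (panel in co$truth$panels) {
      grs <- rowSums(co$genotypes$dosage[, panel, drop = FALSE])
      pv <- stats::cor.test(grs, dbfm)$p.value
      n_sig <- n_sig + (pv < 0.01)
    }
  }
  # Binomial(150, 0.01): P(X > 7) ~ 3e-5
  expect_lte(n_sig, 7)
})

test_that("generated genotypes are HWE-consistent", {
  co <- synthesize_cohort(cohort_config(n_participants = 10000,
                                        n_snps = 100,
                                        panel_sizes = c(5, 5, 5),
                                        missing_rate = 0, seed = 17,
                                        baseline_weeks = 1,
                                        observation_weeks = 1))
  p <- hwe_consistency_check(co)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("monomorphic SNPs get HWE p = 1", {
  co <- synthesize_cohort(small_config(seed = 2))
  co$genotypes$dosage[, 1] <- 0L
  expect_equal(unname(hwe_consistency_check(co)[1]), 1)
})

test_that("planted excess homozygosity is detected", {
  co <- synthesize_cohort(cohort_config(n_participants = 2000, n_snps = 40,
                                        panel_sizes = c(5, 5, 5),
                                        missing_rate = 0, hom_excess = 0.5,
                                        seed = 19, baseline_weeks = 1,
                                        observation_weeks = 1))
  expect_lt(median(hwe_consistency_check(co)), 0.05)
})

test_that("group lifestyle shifts match the configured means", {
  co <- synthesize_cohort(cohort_config(n_participants = 4000, seed = 29,
                                        n_snps = 20, panel_sizes = c(2, 2, 2),
                                        baseline_weeks = 1,
                                        observation_weeks = 1))
  tr <- merge(co$truth$deltas, co$phenotypes[, c("participant_id", "group")])
  mean_by <- function(col, grp) mean(tr[[col]][tr$group == grp])
  expect_equal(mean_by("delta_c", "low_carb"), -24.1, tolerance = 2)
  expect_equal(mean_by("delta_f", "low_fat"), -16.87, tolerance = 1.5)
  expect_equal(mean_by("delta_e", "intense_exercise"), 31.21,
               tolerance = 1.5)
  expect_equal(mean_by("delta_e", "moderate_exercise"), 22.75,
               tolerance = 1.5)
  # off-target deltas are centred at zero
  expect_equal(mean_by("delta_c", "intense_exercise"), 0, tolerance = 2)
})

test_that("diary-estimated deltas track the planted personal shifts", {
  co <- synthesize_cohort(small_config(seed = 37))
  win <- study_windows(co$config)
  est <- compute_lifestyle_delta(co$diet, co$activity, win$baseline,
                                 win$observation)
  tr <- co$truth$deltas[match(est$participant_id,
                              co$truth$deltas$participant_id), ]
  expect_true(all(est$included))
  expect_gt(stats::cor(est$delta_c, tr$delta_c), 0.8)
  expect_gt(stats::cor(est$delta_f, tr$delta_f), 0.8)
  expect_gt(stats::cor(est$delta_e, tr$delta_e), 0.8)
})
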