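test_that("find_cutoff separates two obvious clusters", {
  res <- find_cutoff(scores = c(1, 2, 9, 10),
                     delta_bfm = c(-2, -2, 1, 1), min_class_size = 2)
  expect_equal(res$cutoff, 5.5)
  expect_equal(abs(res$mean_diff), 3)
  expect_equal(res$n_high, 2)
  expect_identical(unname(res$labels), c("low", "low", "high", "high"))
})

test_that("find_cutoff ties fall toward the median cutoff", {
  # constant outcome: every candidate ties at 0 difference
  res <- find_cutoff(scores = c(1, 2, 3, 10), delta_bfm = rep(1, 4),
                     min_class_size = 2)
  cands <- c(1.5, 2.5, 6.5)
  med <- median(c(1, 2, 3, 10))   # 2.5
  expect_equal(res$cutoff, cands[which.min(abs(cands - med))])
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("find_cutoff validates degenerate inputs", {
  expect_error(find_cutoff(rep(1, 30), rnorm(30), min_class_size = 2),
               "distinct")
  expect_error(find_cutoff(1:10, rnorm(10), min_class_size = 8),
               "2 \\* min_class_size")
})

test_that("find_cutoff equals exhaustive enumeration on small instances", {
  set.seed(97)
  for (rep in 1:200) {
    n <- sample(6:12, 1)
    scores <- round(rnorm(n), 2)
    if (length(unique(scores)) < 2) next
    dbfm <- round(rnorm(n), 2)
    mcs <- sample(2:3, 1)
    got <- tryCatch(
      find_cutoff(scores, dbfm, min_class_size = mcs),
      error = function(e) NULL)
    want <- oracle_cutoff(scores, dbfm, mcs)
    if (is.null(got)) {
      expect_null(want)
    } else {
      expect_equal(got$cutoff, want)
    }
  }
})

test_that("t_stat criterion is also supported", {
  set.seed(99)
  scores <- rnorm(60)
  dbfm <- rnorm(60) - (scores > 0)
  res <- find_cutoff(scores, dbfm, min_class_size = 10,
                     criterion = "t_stat")
  want <- oracle_cutoff(scores, dbfm, 10, criterion = "t_stat")
  expect_equal(res$cutoff, want)
})

test_that("fdr_adjust reproduces the worked three-test example", {
  q <- fdr_adjust(c(0.210, 0.250, 2.90e-3))
  expect_equal(round(q, 4), c(0.2500, 0.2500, 0.0087))
})

test_that("fdr_adjust is the BH step-up procedure", {
  expect_equal(fdr_adjust(0.03), 0.03)   # m = 1 identity
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(103)
  for (rep in 1:50) {
    m <- sample(1:20, 1)
    p <- runif(m)
    q <- fdr_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone non-decreasing in sorted-p order, bounded by [max term, 1]
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1) && all(q >= p - 1e-12))
  }
})

test_that("four_group_anova matches planted separations", {
  set.seed(107)
  lab_g <- rep(c("high", "low"), each = 40)
  lab_a <- rep(c("active", "inactive"), times = 40)
  means <- c("high-active" = -2, "high-inactive" = -1,
             "low-active" = -1, "low-inactive" = 0)
  y <- means[paste(lab_g, lab_a, sep = "-")] + rnorm(80, 0, 0.01)
  res <- four_group_anova(lab_g, lab_a, y)
  expect_lt(res$p, 1e-6)
  expect_equal(unname(res$cell_means["high-active"]), -2,
               tolerance = 0.01)

  # identical values everywhere: zero between-group variance
  res0 <- four_group_anova(lab_g, lab_a, rep(1, 80))
  expect_equal(res0$F, 0)

  expect_error(four_group_anova(rep("high", 20),
                                rep(c("active", "inactive"), 10),
                                rnorm(20)),
               "low-active")
})

test_that("four_group_anova rejects at the nominal rate under the null", {
  set.seed(109)
  lab_g <- rep(c("high", "low"), each = 80)
  lab_a <- rep(c("active", "inactive"), times = 80)
  rej <- mean(replicate(1000, {
    four_group_anova(lab_g, lab_a, rnorm(160, 0, 1))$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("paired table is exact on identity and matches the closed form", {
  set.seed(113)
  n <- 40
  phen <- data.frame(weight_pre = rnorm(n, 73, 13),
                     bfm_pre = rnorm(n, 19, 6))
  phen$weight_post <- phen$weight_pre
  phen$bfm_post <- phen$bfm_pre
  tab <- paired_prepost_table(phen)
  expect_equal(tab$mean_diff, c(0, 0))
  expect_equal(tab$p_value, c(1, 1))

  # closed-form |t| = |mean diff| / (sd diff / sqrt(n))
  phen$bfm_post <- phen$bfm_pre + rnorm(n, -0.57, 1.76)
  tab2 <- paired_prepost_table(phen)
  row <- tab2[tab2$variable == "Body fat mass (kg)", ]
  expect_equal(abs(row$t),
               abs(row$mean_diff) / (row$sd_diff / sqrt(row$n)),
               tolerance = 1e-10)
})

test_that("a BFM drop of the reported size is detected at n = 259", {
  # planted mean drop 0.5 kg, sd 1.8: paired t should reject at 0.01
  set.seed(127)
  hits <- mean(replicate(200, {
    pre <- rnorm(259, 19.1, 6.1)
    phen <- data.frame(bfm_pre = pre,
                       bfm_post = pre + rnorm(259, -0.5, 1.8))
    paired_prepost_table(phen)$p_value < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("variables with too few pairs are NA with a warning", {
  phen <- data.frame(bfm_pre = c(19, NA, NA), bfm_post = c(18, NA, NA),
                     whr_pre = c(0.87, 0.9, 0.8),
                     whr_post = c(0.86, 0.89, 0.81))
  expect_warning(tab <- paired_prepost_table(phen), "Body fat mass")
  expect_true(is.na(tab$p_value[tab$variable == "Body fat mass (kg)"]))
  expect_false(is.na(tab$p_value[tab$variable == "Waist hip ratio"]))
})

test_that("group summary tests: Welch t and Pearson chi-squared", {
  m <- matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE)
  res <- group_summary_test(m)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$p, 0.009823, tolerance = 1e-3)

  set.seed(131)
  x <- rnorm(2000)
  g <- rep(c("a", "b"), 1000)
  res2 <- group_summary_test(x, g)
  expect_identical(res2$test, "welch_t")
  expect_gt(res2$p, 0.05)
  expect_equal(res2$p,
               stats::t.test(x[g == "a"], x[g == "b"])$p.value,
               tolerance = 1e-10)

  expect_error(group_summary_test(matrix(c(0, 0, 5, 5), 2)), "all-zero")
  expect_error(group_summary_test(rep(1, 10), rep(c("a", "b"), 5)),
               "zero-variance")
})
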