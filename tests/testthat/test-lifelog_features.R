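# date helpers: study days start on a Monday
d0 <- as.Date("2021-03-01")
bwin <- c(d0, d0 + 13)           # 2-week baseline
owin <- c(d0 + 14, d0 + 27)      # 2-week observation

make_diet <- function(id, dates, carb, fat = 50, prot = 60) {
  data.frame(participant_id = id, date = dates, meal = "lunch",
             carb_g = carb, fat_g = fat, protein_g = prot,
             kcal = 4 * (carb + prot) + 9 * fat, stringsAsFactors = FALSE)
}
make_act <- function(id, dates, kcal) {
  data.frame(participant_id = id, date = dates, kcal_expended = kcal,
             minutes = 30, intensity_frac = 0.6, stringsAsFactors = FALSE)
}

test_that("deltas are observation minus baseline daily means", {
  days_b <- seq(bwin[1], bwin[2], by = 1)
  days_o <- seq(owin[1], owin[2], by = 1)
  diet <- rbind(make_diet("P1", days_b, carb = 300),
                make_diet("P1", days_o, carb = 275.9))
  act <- rbind(make_act("P1", days_b, 200), make_act("P1", days_o, 230))
  res <- compute_lifestyle_delta(diet, act, bwin, owin, min_days = 7)
  expect_equal(res$delta_c, -24.1, tolerance = 1e-10)
  expect_equal(res$delta_f, 0)
  expect_equal(res$delta_e, 30)
  expect_true(res$included)

  # meals summed within a day: two half-sized meals equal one record
  diet2 <- rbind(make_diet("P1", days_b, carb = 150),
                 make_diet("P1", days_b, carb = 150),
                 make_diet("P1", days_o, carb = 275.9 / 2),
                 make_diet("P1", days_o, carb = 275.9 / 2))
  res2 <- compute_lifestyle_delta(diet2, act, bwin, owin, min_days = 7)
  expect_equal(res2$delta_c, -24.1, tolerance = 1e-10)
})

test_that("identical diaries in both windows give zero deltas", {
  days <- seq(bwin[1], owin[2], by = 1)
  diet <- make_diet("P1", days, carb = 280, fat = 70)
  act <- make_act("P1", days, 180)
  res <- compute_lifestyle_delta(diet, act, bwin, owin, min_days = 7)
  expect_equal(res$delta_c, 0)
  expect_equal(res$delta_f, 0)
  expect_equal(res$delta_e, 0)
})

test_that("participants under the coverage floor are flagged out", {
  days_b3 <- seq(bwin[1], bwin[1] + 2, by = 1)     # 3-day baseline
  days_o <- seq(owin[1], owin[2], by = 1)
  diet <- rbind(make_diet("P1", days_b3, 300), make_diet("P1", days_o, 280))
  act <- rbind(make_act("P1", days_b3, 200), make_act("P1", days_o, 220))
  res <- compute_lifestyle_delta(diet, act, bwin, owin, min_days = 7)
  expect_false(res$included)
  expect_equal(res$n_baseline_days, 3)
  # the delta itself is still computed from the days that exist
  expect_equal(res$delta_c, -20)
})

test_that("shifting observation intake by +k shifts the delta by +k", {
  set.seed(5)
  days_b <- seq(bwin[1], bwin[2], by = 1)
  days_o <- seq(owin[1], owin[2], by = 1)
  carb_b <- runif(length(days_b), 200, 400)
  carb_o <- runif(length(days_o), 200, 400)
  act <- rbind(make_act("P1", days_b, 200), make_act("P1", days_o, 200))
  base <- compute_lifestyle_delta(
    rbind(make_diet("P1", days_b, carb_b), make_diet("P1", days_o, carb_o)),
    act, bwin, owin)
  shifted <- compute_lifestyle_delta(
    rbind(make_diet("P1", days_b, carb_b),
          make_diet("P1", days_o, carb_o + 17.5)),
    act, bwin, owin)
  expect_equal(shifted$delta_c, base$delta_c + 17.5, tolerance = 1e-10)
})

test_that("missing participants raise an error when ids are supplied", {
  days <- seq(bwin[1], owin[2], by = 1)
  diet <- make_diet("P1", days, 300)
  act <- make_act("P1", days, 200)
  expect_error(
    compute_lifestyle_delta(diet, act, bwin, owin,
                            participants = c("P1", "P9")),
    "P9")
})

test_that("classify_activity splits at the group median, adherent side", {
  deltas <- data.frame(
    participant_id = paste0("P", 1:4),
    delta_c = 0, delta_f = 0, delta_e = c(10, 20, 30, 40),
    included = TRUE, stringsAsFactors = FALSE)
  groups <- data.frame(participant_id = paste0("P", 1:4),
                       group = "moderate_exercise",
                       stringsAsFactors = FALSE)
  res <- classify_activity(deltas, groups)
  expect_identical(res$activity_class, c("inactive", "inactive",
                                         "active", "active"))

  # low-carb: the more negative side is active
  deltas2 <- data.frame(participant_id = c("A", "B"),
                        delta_c = c(-30, -10), delta_f = 0, delta_e = 0,
                        included = TRUE, stringsAsFactors = FALSE)
  res2 <- classify_activity(deltas2, c(A = "low_carb", B = "low_carb"))
  expect_identical(res2$activity_class[res2$participant_id == "A"],
                   "active")
  expect_identical(res2$activity_class[res2$participant_id == "B"],
                   "inactive")
})

test_that("degenerate medians label everyone inactive with a warning", {
  deltas <- data.frame(participant_id = paste0("P", 1:3),
                       delta_c = 0, delta_f = 0, delta_e = c(5, 5, 5),
                       included = TRUE, stringsAsFactors = FALSE)
  groups <- stats::setNames(rep("intense_exercise", 3), paste0("P", 1:3))
  expect_warning(res <- classify_activity(deltas, groups), "degenerate")
  expect_true(all(res$activity_class == "inactive"))
})

test_that("class sizes differ by at most one for distinct deltas", {
  set.seed(23)
  for (n in c(4, 5, 9, 20, 31)) {
    deltas <- data.frame(participant_id = sprintf("P%03d", 1:n),
                         delta_c = sample(seq_len(1000), n), delta_f = 0,
                         delta_e = 0, included = TRUE,
                         stringsAsFactors = FALSE)
    groups <- stats::setNames(rep("low_carb", n), deltas$participant_id)
    res <- classify_activity(deltas, groups)
    tab <- table(res$activity_class)
    expect_lte(abs(sum(res$activity_class == "active") -
                     sum(res$activity_class == "inactive")), 1)
  }
})

test_that("weekly PPPW weights persons equally and respects coverage", {
  days <- seq(d0, d0 + 13, by = 1)
  diet <- rbind(make_diet("P1", days, carb = 100),
                make_diet("P2", days, carb = 200))
  act <- rbind(make_act("P1", days, 150), make_act("P2", days, 250))
  groups <- c(P1 = "low_carb", P2 = "low_carb")
  res <- weekly_pppw(diet, act, groups, start_date = d0,
                     baseline_weeks = 2)
  carb <- res[res$measure == "carb_g", ]
  expect_equal(carb$week, c(1, 2))
  expect_equal(carb$pppw, c(150, 150))
  expect_true(all(carb$baseline))

  # a participant recorded in only one of two weeks contributes only there
  diet2 <- rbind(make_diet("P1", days, carb = 100),
                 make_diet("P2", days[1:7], carb = 200))
  res2 <- weekly_pppw(diet2, act, groups, start_date = d0)
  carb2 <- res2[res2$measure == "carb_g", ]
  expect_equal(carb2$pppw[carb2$week == 1], 150)
  expect_equal(carb2$pppw[carb2$week == 2], 100)
  expect_equal(carb2$n_participants[carb2$week == 2], 1)
})

test_that("weekly PPPW is invariant to record order", {
  set.seed(31)
  days <- seq(d0, d0 + 20, by = 1)
  diet <- rbind(make_diet("P1", days, runif(21, 100, 300)),
                make_diet("P2", days, runif(21, 100, 300)))
  act <- rbind(make_act("P1", days, runif(21, 50, 400)),
               make_act("P2", days, runif(21, 50, 400)))
  groups <- c(P1 = "low_carb", P2 = "low_fat")
  ref <- weekly_pppw(diet, act, groups, start_date = d0)
  perm <- sample(nrow(diet))
  shuffled <- weekly_pppw(diet[perm, ], act[sample(nrow(act)), ], groups,
                          start_date = d0)
  expect_equal(shuffled, ref)
})
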