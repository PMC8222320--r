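# Lifestyle-change quantification from daily diaries. Daily totals (meals
# summed within a day) feed the deltas; days without any record are simply
# absent from the mean, they are not counted as zero intake.

#' Per-participant lifestyle-change deltas
#'
#' Computes each participant's change in mean daily carbohydrate intake
#' (delta_c, g/day), fat intake (delta_f, g/day) and exercise energy
#' expenditure (delta_e, kcal/day) between a baseline and an observation
#' window. Means are over recorded days only; participants with fewer than
#' `min_days` recorded days in either window (in either diary) are flagged
#' `included = FALSE` and should be excluded from model fitting.
#'
#' @param diet Diet diary `data.frame` (see [read_diet_diary()]).
#' @param activity Activity diary `data.frame` (see
#'   [read_activity_diary()]).
#' @param baseline_window,observation_window Length-2 `Date` vectors of
#'   inclusive bounds; the windows must be disjoint and ordered.
#' @param min_days Minimum recorded days per window per diary (default 7).
#' @param participants Optional character vector of expected participant
#'   ids; ids absent from both diaries raise an error.
#' @return `data.frame` with one row per participant seen in either diary:
#'   `participant_id`, `delta_c`, `delta_f`, `delta_e`, `n_baseline_days`,
#'   `n_observation_days`, `included`.
#' @export
compute_lifestyle_delta <- function(diet, activity, baseline_window,
                                    observation_window, min_days = 7,
                                    participants = NULL) {
  baseline_window <- as.Date(baseline_window)
  observation_window <- as.Date(observation_window)
  if (baseline_window[2] >= observation_window[1]) {
    stop("baseline window must end before the observation window starts")
  }
  if (!is.null(participants)) {
    seen <- union(unique(diet$participant_id),
                  unique(activity$participant_id))
    absent <- setdiff(participants, seen)
    if (length(absent)) {
      stop("participant(s) absent from both diaries: ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
  }

  dt <- data.table::as.data.table(diet)
  daily <- dt[, list(carb = sum(carb_g), fat = sum(fat_g)),
              by = list(participant_id, date)]
  daily[, window := date_window(date, baseline_window, observation_window)]
  diet_sum <- daily[!is.na(window),
                    list(carb = mean(carb), fat = mean(fat),
                         days = .N),
                    by = list(participant_id, window)]

  at <- data.table::as.data.table(activity)
  act_daily <- at[, list(kcal = sum(kcal_expended)),
                  by = list(participant_id, date)]
  act_daily[, window := date_window(date, baseline_window,
                                    observation_window)]
  act_sum <- act_daily[!is.na(window),
                       list(kcal = mean(kcal), days = .N),
                       by = list(participant_id, window)]

  wide <- function(s, value) {
    b <- s[window == "baseline"]
    o <- s[window == "observation"]
    out <- merge(
      data.table::data.table(participant_id = b$participant_id,
                             base = b[[value]], base_days = b$days),
      data.table::data.table(participant_id = o$participant_id,
                             obs = o[[value]], obs_days = o$days),
      by = "participant_id", all = TRUE)
    out
  }
  carb_w <- wide(diet_sum, "carb")
  fat_w <- wide(diet_sum, "fat")
  kcal_w <- wide(act_sum, "kcal")

  all_ids <- sort(union(carb_w$participant_id, kcal_w$participant_id))
  res <- data.frame(participant_id = all_ids, stringsAsFactors = FALSE)
  mi <- function(w, col) w[[col]][match(all_ids, w$participant_id)]
  res$delta_c <- mi(carb_w, "obs") - mi(carb_w, "base")
  res$delta_f <- mi(fat_w, "obs") - mi(fat_w, "base")
  res$delta_e <- mi(kcal_w, "obs") - mi(kcal_w, "base")
  diet_base <- zero_na(mi(carb_w, "base_days"))
  diet_obs <- zero_na(mi(carb_w, "obs_days"))
  act_base <- zero_na(mi(kcal_w, "base_days"))
  act_obs <- zero_na(mi(kcal_w, "obs_days"))
  res$n_baseline_days <- pmin(diet_base, act_base)
  res$n_observation_days <- pmin(diet_obs, act_obs)
  res$included <- diet_base >= min_days & diet_obs >= min_days &
    act_base >= min_days & act_obs >= min_days &
    is.finite(res$delta_c) & is.finite(res$delta_f) & is.finite(res$delta_e)
  res
}

date_window <- function(date, baseline_window, observation_window) {
  w <- rep(NA_character_, length(date))
  w[date >= baseline_window[1] & date <= baseline_window[2]] <- "baseline"
  w[date >= observation_window[1] & date <= observation_window[2]] <-
    "observation"
  w
}

zero_na <- function(x) {
  x[is.na(x)] <- 0
  x
}

# which delta matches which modification group / GRS type
GROUP_DELTA <- c(low_carb = "delta_c", low_fat = "delta_f",
                 moderate_exercise = "delta_e", intense_exercise = "delta_e")
GRS_GROUPS <- list(C = "low_carb", F = "low_fat",
                   E = c("moderate_exercise", "intense_exercise"))

#' Classify lifestyle compliance as active vs inactive
#'
#' Median split of the group-matched lifestyle delta, in the
#' guidance-adherent direction: for diet-modification groups the matched
#' delta is the targeted nutrient change and *active* is the more negative
#' side (larger reduction); for exercise groups it is the expenditure change
#' and *active* is the larger side. Participants exactly at the median are
#' assigned to the active class. A group whose deltas are all identical is
#' degenerate: everyone is labelled inactive, with a warning.
#'
#' @param deltas Output of [compute_lifestyle_delta()].
#' @param groups Named character vector or `data.frame`
#'   (`participant_id`, `group`) giving each participant's modification
#'   group.
#' @return `data.frame`: `participant_id`, `group`, `matched_delta`,
#'   `activity_class` ("active"/"inactive").
#' @export
classify_activity <- function(deltas, groups) {
  if (is.data.frame(groups)) {
    grp <- groups$group[match(deltas$participant_id, groups$participant_id)]
  } else {
    grp <- unname(groups[deltas$participant_id])
  }
  if (any(is.na(grp))) stop("every participant needs a modification group")
  bad <- setdiff(unique(grp), names(GROUP_DELTA))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))

  out <- data.frame(participant_id = deltas$participant_id, group = grp,
                    matched_delta = NA_real_,
                    activity_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 2) stop("need >= 2 participants per group, got ",
                              length(sel), " in ", g)
    d <- deltas[[GROUP_DELTA[[g]]]][sel]
    out$matched_delta[sel] <- d
    med <- stats::median(d, na.rm = TRUE)
    if (all(d == d[1], na.rm = TRUE)) {
      warning("degenerate median in group ", g,
              ": all deltas identical, labelling all inactive")
      out$activity_class[sel] <- "inactive"
      next
    }
    adherent_low <- g %in% c("low_carb", "low_fat")
    active <- if (adherent_low) d <= med else d >= med
    out$activity_class[sel] <- ifelse(active, "active", "inactive")
  }
  out
}

#' Weekly per-person-per-week (PPPW) compliance series
#'
#' Buckets diary records into consecutive 7-day weeks counted from the
#' first study date, then reports, per modification group and week, the
#' mean over participants of each participant's within-week daily mean:
#' carbohydrate g, fat g, and kcal expended. Only participants with at
#' least one record in a week contribute to that week's mean.
#'
#' @param diet,activity Diary data frames.
#' @param groups Participant-to-group mapping as in [classify_activity()].
#' @param start_date First study date; defaults to the earliest diary date.
#' @param baseline_weeks Number of initial weeks flagged as baseline
#'   (default 2).
#' @return `data.frame`: `group`, `week`, `measure` (carb_g / fat_g /
#'   kcal_expended), `pppw`, `n_participants`, `baseline`.
#' @export
weekly_pppw <- function(diet, activity, groups, start_date = NULL,
                        baseline_weeks = 2) {
  if (is.data.frame(groups)) {
    gmap <- stats::setNames(groups$group, groups$participant_id)
  } else {
    gmap <- groups
  }
  start_date <- if (is.null(start_date)) {
    min(c(diet$date, activity$date))
  } else as.Date(start_date)

  one <- function(df, value_col, measure) {
    dt <- data.table::as.data.table(df)
    dt[, val := dt[[value_col]]]
    daily <- dt[, list(val = sum(val)), by = list(participant_id, date)]
    daily[, week := as.integer(floor(as.numeric(date - start_date) / 7)) + 1L]
    per_part <- daily[, list(val = mean(val)),
                      by = list(participant_id, week)]
    per_part[, group := gmap[participant_id]]
    out <- per_part[, list(pppw = mean(val), n_participants = .N),
                    by = list(group, week)]
    out[, measure := measure]
    out
  }
  res <- data.table::rbindlist(list(one(diet, "carb_g", "carb_g"),
                                    one(diet, "fat_g", "fat_g"),
                                    one(activity, "kcal_expended",
                                        "kcal_expended")))
  res[, baseline := week <= baseline_weeks]
  data.table::setorder(res, measure, group, week)
  as.data.frame(res[, list(group, week, measure, pppw, n_participants,
                           baseline)])
}
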