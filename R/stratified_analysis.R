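# High/low GRS stratification and the statistical comparison layer.

#' Welch two-sample t-test (closed form)
#'
#' Unequal-variance t-test used throughout the stratification layer.
#' Degenerate inputs (both groups constant) return t = 0, p = 1 when the
#' means agree and |t| = Inf, p = 0 otherwise, instead of erroring.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return List: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs >= 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    t <- if (mx == my) 0 else sign(mx - my) * Inf
    return(list(t = t, df = NA_real_, p = if (mx == my) 1 else 0,
                mean_x = mx, mean_y = my))
  }
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_x = mx,
       mean_y = my)
}

#' Data-driven high/low GRS cutoff
#'
#' Scans all candidate cutoffs (midpoints between consecutive distinct
#' sorted scores) whose high and low classes both reach `min_class_size`,
#' and picks the one maximizing the absolute difference in mean BFM change
#' between classes (`criterion = "mean_diff"`, default) or the absolute
#' Welch t statistic (`"t_stat"`). Ties are broken toward the cutoff
#' closest to the score median (then toward the lower cutoff). The chosen
#' split is reported with a Welch two-sample t-test.
#'
#' @param scores Numeric GRS values, one per participant.
#' @param delta_bfm BFM change (kg, post minus pre), aligned with `scores`.
#' @param min_class_size Minimum participants per class; default
#'   `max(10, ceiling(0.1 * n))`.
#' @param criterion `"mean_diff"` or `"t_stat"`.
#' @return A `stratification_result` list: `cutoff`, `n_high`, `n_low`,
#'   `mean_high`, `mean_low`, `mean_diff`, `t`, `df`, `p`, `criterion`,
#'   `labels` (per-participant "high"/"low").
#' @export
find_cutoff <- function(scores, delta_bfm, min_class_size = NULL,
                        criterion = c("mean_diff", "t_stat")) {
  criterion <- match.arg(criterion)
  n <- length(scores)
  if (length(delta_bfm) != n) stop("scores and delta_bfm lengths differ")
  if (anyNA(scores) || anyNA(delta_bfm)) stop("inputs must not contain NA")
  if (is.null(min_class_size)) min_class_size <- max(10, ceiling(0.1 * n))
  min_class_size <- max(2, min_class_size)   # Welch test needs >= 2 per class
  if (n < 2 * min_class_size) {
    stop("need at least 2 * min_class_size participants")
  }
  uq <- sort(unique(scores))
  if (length(uq) < 2) stop("need at least 2 distinct scores")
  cands <- (uq[-1] + uq[-length(uq)]) / 2

  stat <- vapply(cands, function(cut) {
    hi <- scores > cut
    n_hi <- sum(hi); n_lo <- n - n_hi
    if (n_hi < min_class_size || n_lo < min_class_size) return(NA_real_)
    if (criterion == "mean_diff") {
      abs(mean(delta_bfm[hi]) - mean(delta_bfm[!hi]))
    } else {
      abs(welch_t(delta_bfm[hi], delta_bfm[!hi])$t)
    }
  }, numeric(1))
  if (all(is.na(stat))) {
    stop("no cutoff satisfies the minimum class size")
  }
  best <- max(stat, na.rm = TRUE)
  tol <- 1e-10 * max(1, abs(best))
  tied <- which(!is.na(stat) & stat >= best - tol)
  med <- stats::median(scores)
  tied <- tied[order(abs(cands[tied] - med), cands[tied])]
  cut <- cands[tied[1]]

  hi <- scores > cut
  tt <- welch_t(delta_bfm[hi], delta_bfm[!hi])
  structure(
    list(cutoff = cut, n_high = sum(hi), n_low = sum(!hi),
         mean_high = tt$mean_x, mean_low = tt$mean_y,
         mean_diff = tt$mean_x - tt$mean_y,
         t = tt$t, df = tt$df, p = tt$p, criterion = criterion,
         labels = ifelse(hi, "high", "low")),
    class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<stratification_result> cutoff %.4g (%s)\n",
    "  high: n=%d mean dBFM %.3f | low: n=%d mean dBFM %.3f\n",
    "  Welch t = %.3f, p = %.4g\n"),
    x$cutoff, x$criterion, x$n_high, x$mean_high, x$n_low, x$mean_low,
    x$t, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/rank, running minima are taken from the largest rank down, and values
#' are capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' One-way ANOVA over the four GRS-by-compliance groups
#'
#' Crosses the high/low GRS class with the active/inactive lifestyle class
#' and tests the BFM change across the four resulting cells with a one-way
#' fixed-effects ANOVA.
#'
#' @param grs_class Character vector, "high"/"low" per participant.
#' @param activity_class Character vector, "active"/"inactive".
#' @param delta_bfm BFM change (kg), same length.
#' @return A `four_group_result` list: `cell_means`, `cell_n`, `F`,
#'   `df_between`, `df_within`, `p`.
#' @export
four_group_anova <- function(grs_class, activity_class, delta_bfm) {
  n <- length(delta_bfm)
  if (length(grs_class) != n || length(activity_class) != n) {
    stop("inputs must have equal length")
  }
  cells <- c("high-active", "high-inactive", "low-active", "low-inactive")
  lab <- paste(grs_class, activity_class, sep = "-")
  bad <- setdiff(unique(lab), cells)
  if (length(bad)) stop("unknown class combination(s): ",
                        paste(bad, collapse = ", "))
  empty <- setdiff(cells, unique(lab))
  if (length(empty)) {
    stop("empty cell(s): ", paste(empty, collapse = ", "))
  }
  f <- factor(lab, levels = cells)
  if (stats::var(delta_bfm) == 0) {
    # no between-group variance at all
    return(structure(
      list(cell_means = tapply(delta_bfm, f, mean),
           cell_n = as.integer(table(f)),
           F = 0, df_between = 3L, df_within = n - 4L, p = 1),
      class = "four_group_result"))
  }
  fit <- stats::lm(delta_bfm ~ f)
  av <- stats::anova(fit)
  structure(
    list(cell_means = tapply(delta_bfm, f, mean),
         cell_n = as.integer(table(f)),
         F = av$`F value`[1], df_between = av$Df[1], df_within = av$Df[2],
         p = av$`Pr(>F)`[1]),
    class = "four_group_result")
}

#' @export
print.four_group_result <- function(x, ...) {
  cat("<four_group_result>\n")
  for (i in seq_along(x$cell_means)) {
    cat(sprintf("  %-14s n=%-4d mean dBFM %.3f\n",
                names(x$cell_means)[i], x$cell_n[i], x$cell_means[i]))
  }
  cat(sprintf("  ANOVA F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

# pretty label, pre column, post column
PREPOST_VARIABLES <- list(
  c("Weight (kg)", "weight_pre", "weight_post"),
  c("Body fat mass (kg)", "bfm_pre", "bfm_post"),
  c("Body fat percentage (%)", "bfp_pre", "bfp_post"),
  c("Body mass index (kg/m2)", "bmi_pre", "bmi_post"),
  c("Skeletal muscle mass (kg)", "smm_pre", "smm_post"),
  c("Waist hip ratio", "whr_pre", "whr_post"),
  c("Triglycerides (mg/dL)", "tg_pre", "tg_post"),
  c("LDL-Cholesterol (mg/dL)", "ldl_pre", "ldl_post"),
  c("HDL-Cholesterol (mg/dL)", "hdl_pre", "hdl_post"))

#' Paired pre/post comparison table
#'
#' For every anthropometric and serologic variable with paired pre/post
#' columns present in the phenotype table, reports baseline and
#' post-observation mean and SD, the mean and SD of the within-person
#' difference (post minus pre), and a two-sided paired t-test p-value.
#' Variables with fewer than two complete pairs are reported as NA with a
#' warning.
#'
#' @param phenotypes Phenotype `data.frame`.
#' @return `data.frame`: `variable`, `n`, `mean_pre`, `sd_pre`,
#'   `mean_post`, `sd_post`, `mean_diff`, `sd_diff`, `t`, `p_value`.
#' @export
paired_prepost_table <- function(phenotypes) {
  vars <- Filter(function(v) all(v[2:3] %in% names(phenotypes)),
                 PREPOST_VARIABLES)
  if (!length(vars)) stop("no pre/post variable pairs found")
  rows <- lapply(vars, function(v) {
    pre <- phenotypes[[v[2]]]
    post <- phenotypes[[v[3]]]
    ok <- stats::complete.cases(pre, post)
    out <- data.frame(variable = v[1], n = sum(ok), mean_pre = NA_real_,
                      sd_pre = NA_real_, mean_post = NA_real_,
                      sd_post = NA_real_, mean_diff = NA_real_,
                      sd_diff = NA_real_, t = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(ok) < 2) {
      warning("fewer than 2 complete pairs for ", v[1])
      return(out)
    }
    pre <- pre[ok]; post <- post[ok]; d <- post - pre
    out$mean_pre <- mean(pre); out$sd_pre <- stats::sd(pre)
    out$mean_post <- mean(post); out$sd_post <- stats::sd(post)
    out$mean_diff <- mean(d); out$sd_diff <- stats::sd(d)
    if (stats::sd(d) == 0) {
      out$t <- 0; out$p_value <- 1
    } else {
      tt <- stats::t.test(post, pre, paired = TRUE)
      out$t <- unname(tt$statistic); out$p_value <- tt$p.value
    }
    out
  })
  do.call(rbind, rows)
}

#' Two-group summary test
#'
#' Welch t-test for a continuous variable split by a two-level group, or
#' Pearson chi-squared (no continuity correction) when given a contingency
#' table.
#'
#' @param x Numeric vector (continuous case) or a matrix/table
#'   (categorical case).
#' @param group Two-level grouping vector; ignored for tables.
#' @return List: `test` ("welch_t" or "chi_squared"), `statistic`, `df`,
#'   `p`.
#' @export
group_summary_test <- function(x, group = NULL) {
  if (is.matrix(x) || is.table(x)) {
    m <- as.matrix(x)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      stop("contingency table has an all-zero row or column")
    }
    ct <- stats::chisq.test(m, correct = FALSE)
    return(list(test = "chi_squared", statistic = unname(ct$statistic),
                df = unname(ct$parameter), p = ct$p.value))
  }
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  xs <- split(x, g)
  if (stats::var(xs[[1]]) == 0 && stats::var(xs[[2]]) == 0) {
    stop("zero-variance continuous input")
  }
  tt <- welch_t(xs[[1]], xs[[2]])
  list(test = "welch_t", statistic = tt$t, df = tt$df, p = tt$p)
}
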