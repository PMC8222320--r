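# End-to-end orchestration: simulate (or load) -> QC -> lifelog -> fit ->
# score -> stratify, with every intermediate written to the output
# directory and a JSON manifest tying the run together.

#' Build a pipeline run configuration
#'
#' Either point the pipeline at existing exchange files (`genotypes`,
#' `phenotypes`, `diet`, `activity`) or leave them NULL to simulate a
#' cohort with [synthesize_cohort()] first. All paths are validated before
#' any stage runs.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed used for simulation.
#' @param cohort Named list of [cohort_config()] overrides (simulation
#'   mode only).
#' @param genotypes,phenotypes,diet,activity Input file paths (load mode).
#' @param genotype_format `"vcf"` or `"traw"`.
#' @param call_rate_min,maf_min,hwe_p_min QC thresholds, see [apply_qc()].
#' @param baseline_weeks,observation_weeks Study period lengths.
#' @param start_date First study date; default: earliest diary date.
#' @param min_days Diary coverage floor, see [compute_lifestyle_delta()].
#' @param panel_sizes GRS panel sizes (C, F, E).
#' @param criterion Cutoff-search criterion, see [find_cutoff()].
#' @param min_class_frac Minimum class size as a fraction of the cohort
#'   (floored at 10 participants).
#' @param missing_policy Scoring policy for missing dosages.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 42L, cohort = list(),
                       genotypes = NULL, phenotypes = NULL, diet = NULL,
                       activity = NULL, genotype_format = c("vcf", "traw"),
                       call_rate_min = 0.99, maf_min = 0.01,
                       hwe_p_min = 1e-5, baseline_weeks = 2,
                       observation_weeks = 12, start_date = NULL,
                       min_days = 7, panel_sizes = c(C = 37, F = 19, E = 25),
                       criterion = c("mean_diff", "t_stat"),
                       min_class_frac = 0.10,
                       missing_policy = c("mean_impute", "drop_snp")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              genotypes = genotypes, phenotypes = phenotypes, diet = diet,
              activity = activity,
              genotype_format = match.arg(genotype_format),
              call_rate_min = call_rate_min, maf_min = maf_min,
              hwe_p_min = hwe_p_min,
              baseline_weeks = as.integer(baseline_weeks),
              observation_weeks = as.integer(observation_weeks),
              start_date = start_date, min_days = min_days,
              panel_sizes = panel_sizes,
              criterion = match.arg(criterion),
              min_class_frac = min_class_frac,
              missing_policy = match.arg(missing_policy))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, QC, lifelog feature extraction, interaction
#' fitting, GRS scoring and stratified analysis in order, writing every
#' intermediate artifact under `config$out_dir` and finishing with a
#' `manifest.json` whose `content_hash` is identical across identical
#' runs. Any stage failure aborts with the stage name; artifacts written
#' so far are retained for debugging.
#'
#' @param config A `run_config` (or a path to a JSON config).
#' @return Invisibly, a list with `status` (0 on success) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[grslife] stage %-9s done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  ## validate / simulate inputs
  simulate <- is.null(config$genotypes)
  if (!simulate) {
    paths <- c(genotypes = config$genotypes, phenotypes = config$phenotypes,
               diet = config$diet, activity = config$activity)
    if (any(vapply(paths, is.null, logical(1)))) {
      stop("load mode needs genotypes, phenotypes, diet and activity paths")
    }
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      stop("input file(s) not found: ",
           paste(missing_files, collapse = ", "))
    }
  } else {
    cc_args <- utils::modifyList(
      list(seed = config$seed, baseline_weeks = config$baseline_weeks,
           observation_weeks = config$observation_weeks),
      config$cohort)
    cohort <- stage("simulate", {
      co <- synthesize_cohort(do.call(cohort_config, cc_args))
      write_cohort(co, file.path(out, "inputs"), config$genotype_format)
      co
    })
    paths <- c(
      genotypes = file.path(out, "inputs",
                            paste0("genotypes.", config$genotype_format)),
      phenotypes = file.path(out, "inputs", "phenotypes.csv"),
      diet = file.path(out, "inputs", "diet.csv"),
      activity = file.path(out, "inputs", "activity.csv"))
  }

  inputs <- stage("read", list(
    gm = read_genotypes(paths[["genotypes"]], config$genotype_format),
    phen = read_phenotypes(paths[["phenotypes"]]),
    diet = read_diet_diary(paths[["diet"]]),
    activity = read_activity_diary(paths[["activity"]])))

  qc <- stage("qc", {
    res <- apply_qc(inputs$gm, config$call_rate_min, config$maf_min,
                    config$hwe_p_min)
    write_qc_report(res$report, out)
    res
  })

  feat <- stage("lifelog", {
    start <- if (is.null(config$start_date)) {
      min(c(inputs$diet$date, inputs$activity$date))
    } else as.Date(config$start_date)
    b_end <- start + 7L * config$baseline_weeks - 1L
    o_end <- b_end + 7L * config$observation_weeks
    deltas <- compute_lifestyle_delta(
      inputs$diet, inputs$activity, c(start, b_end), c(b_end + 1L, o_end),
      min_days = config$min_days,
      participants = inputs$phen$participant_id)
    act <- classify_activity(deltas, inputs$phen[, c("participant_id",
                                                     "group")])
    deltas$activity_class <- act$activity_class
    write_tsv(deltas, file.path(out, "deltas.tsv"))
    weekly <- weekly_pppw(inputs$diet, inputs$activity,
                          inputs$phen[, c("participant_id", "group")],
                          start_date = start,
                          baseline_weeks = config$baseline_weeks)
    write_tsv(weekly, file.path(out, "weekly_pppw.tsv"))
    deltas
  })

  fitres <- stage("fit", {
    cov <- covariate_rows(inputs$phen, feat)
    diet_cov <- cov[cov$group %in% c("low_carb", "low_fat"), ]
    ex_cov <- cov[cov$group %in% c("moderate_exercise",
                                   "intense_exercise"), ]
    diet_w <- fit_interaction_models(qc$genotypes, diet_cov, "diet")
    ex_w <- fit_interaction_models(qc$genotypes, ex_cov, "exercise")
    weights <- as.data.frame(data.table::rbindlist(list(diet_w, ex_w),
                                                   fill = TRUE))
    write_tsv(weights, file.path(out, "weights.tsv"))
    panels <- build_panels(diet_w, ex_w, config$panel_sizes,
                           qc$genotypes$snps)
    write_panels(panels, file.path(out, "panels.json"))
    list(weights = weights, panels = panels)
  })

  scores <- stage("score", {
    sc <- grs_score_all(qc$genotypes, fitres$panels, config$missing_policy)
    write_tsv(sc, file.path(out, "scores.tsv"))
    sc
  })

  analysis <- stage("analyze", {
    analyze_scores(scores, feat, inputs$phen, out,
                   criterion = config$criterion,
                   min_class_frac = config$min_class_frac)
  })

  manifest <- stage("manifest", {
    write_manifest(config, paths, out,
                   counts = list(
                     n_participants = nrow(inputs$phen),
                     n_snps_input = qc$report$n_input,
                     n_snps_retained = qc$report$n_retained,
                     n_deltas_included = sum(feat$included),
                     n_scored = nrow(scores)))
  })
  invisible(list(status = 0L, manifest = manifest))
}

#' Stratified analysis over the three GRS types
#'
#' For each GRS (C, F, E): finds the high/low cutoff over all scored
#' participants, reports the Welch comparison with Benjamini-Hochberg
#' q-values across the three tests, and runs the four-group
#' (GRS x compliance) ANOVA within the modification groups matched to that
#' GRS type. Artifacts: `stratification.tsv`, `four_group.tsv`,
#' `class_data.tsv` (per-participant classes for plotting) and
#' `analysis_summary.json`.
#'
#' @param scores Output of [grs_score_all()].
#' @param deltas Output of [compute_lifestyle_delta()] with an
#'   `activity_class` column.
#' @param phenotypes Phenotype table.
#' @param out Output directory (NULL to skip writing).
#' @param criterion,min_class_frac See [run_config()].
#' @return List with `stratification` (data.frame), `four_group`
#'   (data.frame) and `results` (per-type objects).
#' @export
analyze_scores <- function(scores, deltas, phenotypes, out = NULL,
                           criterion = "mean_diff", min_class_frac = 0.10) {
  delta_bfm <- phenotypes$bfm_post[match(scores$participant_id,
                                         phenotypes$participant_id)] -
    phenotypes$bfm_pre[match(scores$participant_id,
                             phenotypes$participant_id)]
  group <- phenotypes$group[match(scores$participant_id,
                                  phenotypes$participant_id)]
  n <- nrow(scores)
  mcs <- max(10, ceiling(min_class_frac * n))
  types <- c(C = "grs_c", F = "grs_f", E = "grs_e")

  strats <- lapply(types, function(col) {
    find_cutoff(scores[[col]], delta_bfm, min_class_size = mcs,
                criterion = criterion)
  })
  q <- fdr_adjust(vapply(strats, function(s) s$p, numeric(1)))
  strat_tab <- data.frame(
    grs_type = names(types),
    cutoff = vapply(strats, function(s) s$cutoff, numeric(1)),
    n_high = vapply(strats, function(s) s$n_high, numeric(1)),
    n_low = vapply(strats, function(s) s$n_low, numeric(1)),
    mean_dbfm_high = vapply(strats, function(s) s$mean_high, numeric(1)),
    mean_dbfm_low = vapply(strats, function(s) s$mean_low, numeric(1)),
    t = vapply(strats, function(s) s$t, numeric(1)),
    p_value = vapply(strats, function(s) s$p, numeric(1)),
    q_value = q, stringsAsFactors = FALSE)

  act_class <- deltas$activity_class[match(scores$participant_id,
                                           deltas$participant_id)]
  fg_rows <- list()
  fg_results <- list()
  class_rows <- list()
  for (ty in names(types)) {
    grs_lab <- strats[[ty]]$labels
    sel <- which(group %in% GRS_GROUPS[[ty]] & !is.na(act_class))
    class_rows[[ty]] <- data.frame(
      grs_type = ty, participant_id = scores$participant_id,
      grs_class = grs_lab, activity_class = act_class,
      matched_group = group %in% GRS_GROUPS[[ty]],
      delta_bfm = delta_bfm, stringsAsFactors = FALSE)
    fg <- tryCatch(
      four_group_anova(grs_lab[sel], act_class[sel], delta_bfm[sel]),
      error = function(e) e)
    if (inherits(fg, "error")) {
      fg_rows[[ty]] <- data.frame(
        grs_type = ty, cell = NA_character_, n = NA_integer_,
        mean_dbfm = NA_real_, F = NA_real_, p_value = NA_real_,
        note = conditionMessage(fg), stringsAsFactors = FALSE)
    } else {
      fg_results[[ty]] <- fg
      fg_rows[[ty]] <- data.frame(
        grs_type = ty, cell = names(fg$cell_means), n = fg$cell_n,
        mean_dbfm = as.numeric(fg$cell_means), F = fg$F, p_value = fg$p,
        note = NA_character_, stringsAsFactors = FALSE)
    }
  }
  fg_tab <- do.call(rbind, fg_rows)
  rownames(fg_tab) <- NULL

  if (!is.null(out)) {
    write_tsv(strat_tab, file.path(out, "stratification.tsv"))
    write_tsv(fg_tab, file.path(out, "four_group.tsv"))
    write_tsv(do.call(rbind, class_rows), file.path(out, "class_data.tsv"))
    jsonlite::write_json(
      list(stratification = strat_tab, four_group = fg_tab),
      file.path(out, "analysis_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  list(stratification = strat_tab, four_group = fg_tab,
       results = list(stratification = strats, four_group = fg_results))
}

write_manifest <- function(config, input_paths, out, counts) {
  artifacts <- setdiff(list.files(out, recursive = TRUE),
                       "manifest.json")
  art_paths <- file.path(out, artifacts)
  md5 <- tools::md5sum(art_paths)
  names(md5) <- artifacts
  md5 <- md5[order(names(md5))]
  cfg_echo <- config
  cfg_echo$start_date <- if (is.null(config$start_date)) NULL else
    as.character(config$start_date)
  manifest <- list(
    package = "grslife",
    version = as.character(utils::packageVersion("grslife")),
    config = unclass(cfg_echo),
    inputs = as.list(tools::md5sum(unname(input_paths))),
    counts = counts,
    artifacts = as.list(md5),
    content_hash = digest_strings(paste(names(md5), md5, sep = ":")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest
}

# md5 of a character vector via a temp file (no extra dependency)
digest_strings <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
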