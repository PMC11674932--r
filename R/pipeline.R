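# End-to-end orchestration: generate -> measure -> harmonize -> analyze,
# with seeded determinism, logging and file outputs.

#' Pipeline configuration
#'
#' Bundles the cohort generator settings with the measurement, harmonization
#' and statistics options. `seed`, when given, overrides the seed inside the
#' cohort config so one number controls every source of randomness.
#'
#' @param cohort a [cohort_config()].
#' @param cc_exponent brain-volume exponent for [cc_ratio()].
#' @param commissural_weights `"normalized"` or `"raw"`, see
#'   [cohort_metrics()].
#' @param midline midline-region policy for [hemisphere_blocks()].
#' @param combat_mode,combat_tol harmonization options ([fit_combat()]).
#' @param edss_cutoff,sdmt_cutoff,edss_high_inclusive,sdmt_high_inclusive
#'   clinical split options ([split_groups()]).
#' @param seed optional integer overriding `cohort$seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), cc_exponent = 2 / 3,
                            commissural_weights = "normalized",
                            midline = "exclude",
                            combat_mode = "full", combat_tol = 1e-4,
                            edss_cutoff = 3, sdmt_cutoff = 40,
                            edss_high_inclusive = TRUE,
                            sdmt_high_inclusive = TRUE, seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, cc_exponent = cc_exponent,
                 commissural_weights = commissural_weights,
                 midline = midline, combat_mode = combat_mode,
                 combat_tol = combat_tol, edss_cutoff = edss_cutoff,
                 sdmt_cutoff = sdmt_cutoff,
                 edss_high_inclusive = edss_high_inclusive,
                 sdmt_high_inclusive = sdmt_high_inclusive),
            class = "pipeline_config")
}

# Neuroimaging-derived columns harmonized alongside the connectivity
# measures (the clinical scores and demographics are never adjusted).
harmonized_scalars <- c("gmf", "wmf", "lvf", "cc_area", "brain_volume")

#' Harmonize a measured cohort across centers
#'
#' Fits and applies the empirical-Bayes batch correction to the connectivity
#' measure table plus the neuroimaging-derived scalars (GMF, WMF, LVF, CC
#' area, brain volume), with age, sex and diagnosis (HC/MS) as preserved
#' covariates.
#'
#' @param metrics table from [cohort_metrics()].
#' @param records aligned subject table.
#' @param mode,tol passed to [fit_combat()].
#' @return list: `metrics` (harmonized measure table, same shape as input),
#'   `records` (records with harmonized scalar columns), `model`.
#' @export
harmonize_cohort <- function(metrics, records, mode = "full", tol = 1e-4) {
  records <- records[match(metrics$id, records$id), ]
  feat <- cbind(as.matrix(metrics[, setdiff(names(metrics), "id")]),
                as.matrix(records[, harmonized_scalars]))
  covs <- cbind(age = records$age, sex = records$sex,
                diagnosis = as.numeric(records$diagnosis == "MS"))
  model <- fit_combat(feat, records$center, covs, mode = mode, tol = tol)
  harm <- apply_combat(model, feat, records$center, covs)
  out_metrics <- metrics
  metric_cols <- setdiff(names(metrics), "id")
  out_metrics[metric_cols] <- harm[, metric_cols]
  out_records <- records
  out_records[harmonized_scalars] <- harm[, harmonized_scalars]
  list(metrics = out_metrics, records = out_records, model = model)
}

#' Three-group comparisons for every measure
#'
#' Residualizes each measure on age and sex, then runs the one-way three-group
#' ANOVA (HC / low / high) with Tukey HSD post hoc tests for both clinical
#' splits, Bonferroni-correcting the ANOVA p-values within each split family.
#'
#' @param metrics (harmonized) measure table.
#' @param records aligned subject table.
#' @param config a [pipeline_config()] (split options are read from it).
#' @return list: `anova` (one row per measure x split) and `tukey` (all
#'   pairwise rows).
#' @export
run_group_comparisons <- function(metrics, records,
                                  config = pipeline_config()) {
  records <- records[match(metrics$id, records$id), ]
  groups <- split_groups(records, config$edss_cutoff, config$sdmt_cutoff,
                         config$edss_high_inclusive,
                         config$sdmt_high_inclusive)
  measures <- setdiff(names(metrics), "id")
  an_rows <- list()
  tk_rows <- list()
  for (split in names(groups)) {
    g <- groups[[split]]
    for (mv in measures) {
      y <- residualize(metrics[[mv]], records[, c("age", "sex")])
      res <- anova_tukey(y, g)
      an_rows[[length(an_rows) + 1]] <- data.frame(
        split = split, measure = mv, F = res$F, p_raw = res$p,
        p_corrected = NA_real_, n_excluded = attr(g, "n_excluded"),
        stringsAsFactors = FALSE)
      tk <- res$tukey
      tk$split <- split
      tk$measure <- mv
      tk_rows[[length(tk_rows) + 1]] <- tk
    }
  }
  an <- do.call(rbind, an_rows)
  for (s in unique(an$split)) {
    idx <- an$split == s
    an$p_corrected[idx] <- bonferroni(an$p_raw[idx], sum(idx))
  }
  list(anova = an, tukey = do.call(rbind, tk_rows))
}

cfg_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     digits = NA, force = TRUE))
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

annotated_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(paste0("# ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' generate (or load) -> measure -> harmonize -> analyze. Writes, under
#' `out_dir`: `metrics.csv`, `harmonized_metrics.csv`, `harmonized_records.csv`,
#' `combat_model.json`, `correlations.csv`, `anova.csv`, `tukey.csv`,
#' `report.txt`, `config.json` and `run.log`. All CSVs carry a first-line
#' comment with the package version and the config hash; outputs are
#' byte-identical across runs with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param data_dir optional: read the cohort from this directory (written by
#'   [write_cohort()]) instead of generating; missing directory is an error
#'   before any computation.
#' @param write_data also write the generated cohort under
#'   `out_dir/cohort/`.
#' @return invisibly, a list with the in-memory tables (`metrics`,
#'   `harmonized`, `correlations`, `groups`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         data_dir = NULL, write_data = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data_dir does not exist: ", data_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- paste0("hemiconn-", as.character(utils::packageVersion("hemiconn")),
                  " config=", cfg_hash(config))
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  note("[run] ", stamp)

  if (is.null(data_dir)) {
    note("[generate] n=", config$cohort$n_subjects, " seed=",
         config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    if (write_data) write_cohort(cohort, file.path(out_dir, "cohort"))
  } else {
    note("[load] ", data_dir)
    cohort <- read_cohort(data_dir)
    if (length(cohort$connectomes) == 0)
      stop("no valid subjects in ", data_dir, call. = FALSE)
    if (nrow(cohort$excluded) > 0)
      note("[load] WARN excluded=", nrow(cohort$excluded), " ids=",
           paste(cohort$excluded$id, collapse = ","))
  }
  records <- cohort$records

  note("[metrics] measuring ", length(cohort$connectomes), " subjects")
  metrics <- cohort_metrics(cohort$connectomes, records,
                            cc_exponent = config$cc_exponent,
                            midline = config$midline,
                            commissural_weights = config$commissural_weights)
  annotated_csv(metrics, file.path(out_dir, "metrics.csv"), stamp)

  note("[harmonize] mode=", config$combat_mode)
  harm <- harmonize_cohort(metrics, records, mode = config$combat_mode,
                           tol = config$combat_tol)
  annotated_csv(harm$metrics, file.path(out_dir, "harmonized_metrics.csv"),
                stamp)
  annotated_csv(harm$records, file.path(out_dir, "harmonized_records.csv"),
                stamp)
  combat_write_json(harm$model, file.path(out_dir, "combat_model.json"))

  note("[analyze] correlation battery")
  battery <- run_correlation_battery(harm$metrics, harm$records,
                                     center_covariate = FALSE)
  annotated_csv(battery, file.path(out_dir, "correlations.csv"), stamp)

  note("[analyze] group comparisons")
  groups <- run_group_comparisons(harm$metrics, harm$records, config)
  annotated_csv(groups$anova, file.path(out_dir, "anova.csv"), stamp)
  annotated_csv(groups$tukey, file.path(out_dir, "tukey.csv"), stamp)

  splits <- split_groups(records, config$edss_cutoff, config$sdmt_cutoff,
                         config$edss_high_inclusive,
                         config$sdmt_high_inclusive)
  fam <- unique(battery[, c("family", "family_size")])
  report <- c(
    paste0("hemispheric connectivity pipeline report  (", stamp, ")"),
    "",
    sprintf("subjects: %d (MS=%d, HC=%d), centers: %d", nrow(records),
            sum(records$diagnosis == "MS"), sum(records$diagnosis == "HC"),
            length(unique(records$center))),
    sprintf("EDSS split: HC=%d low=%d high=%d excluded=%d",
            sum(splits$edss_group == "HC", na.rm = TRUE),
            sum(splits$edss_group == "low_edss", na.rm = TRUE),
            sum(splits$edss_group == "high_edss", na.rm = TRUE),
            attr(splits$edss_group, "n_excluded")),
    sprintf("SDMT split: HC=%d low=%d high=%d excluded=%d",
            sum(splits$sdmt_group == "HC", na.rm = TRUE),
            sum(splits$sdmt_group == "low_sdmt", na.rm = TRUE),
            sum(splits$sdmt_group == "high_sdmt", na.rm = TRUE),
            attr(splits$sdmt_group, "n_excluded")),
    "",
    "Bonferroni families:",
    sprintf("  %-16s m=%d", fam$family, fam$family_size),
    sprintf("  %-16s m=%d (per split)", "anova",
            sum(groups$anova$split == "edss_group")),
    "",
    "clinical-family partial correlations (corrected):",
    sprintf("  %-40s r=%+.3f p=%.3g", battery$pair[battery$family ==
                                                     "clinical"],
            battery$r[battery$family == "clinical"],
            battery$p_corrected[battery$family == "clinical"]))
  writeLines(report, file.path(out_dir, "report.txt"))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  note("[done] outputs in ", out_dir)
  writeLines(log_lines, log_path)
  invisible(list(metrics = metrics, harmonized = harm, correlations = battery,
                 groups = groups, records = records,
                 ground_truth = cohort$ground_truth, out_dir = out_dir))
}
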