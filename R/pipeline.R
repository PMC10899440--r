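# End-to-end orchestration: simulate (or load) a cohort, summarize and
# exclude, fit every subject, build learning curves and growth fits, run
# the group statistics battery, and optionally write a reproducible
# report bundle with a content-hash manifest. Every stage is a pure
# function of (inputs, config, seed).

#' Pipeline configuration
#'
#' @param cohort an [cohort_config()] used to simulate data, or `NULL`
#'   when reading real logs.
#' @param trials_path,subjects_path CSV paths of an existing trial log
#'   and demographics table; when given, simulation is skipped.
#' @param fit list of arguments for [rlwm_fit()] (e.g. `n_starts`,
#'   `K_grid`, `fixed`).
#' @param analysis list: `exclusion_threshold`, `family_size` (Bonferroni
#'   family for the 4-parameter comparison tables), `cutoffs` (classifier
#'   age cutoffs), `initiation_fraction`.
#' @param seed master seed for fitting and analysis randomness.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            trials_path = NULL, subjects_path = NULL,
                            fit = list(), analysis = list(), seed = 1L) {
  if (is.null(cohort) && is.null(trials_path))
    stopf("either a cohort config or a trials_path is required")
  if (!is.null(trials_path) && is.null(subjects_path))
    stopf("trials_path requires subjects_path")
  for (p in c(trials_path, subjects_path))
    if (!is.null(p) && !file.exists(p)) stopf("path does not exist: %s", p)
  analysis <- modifyList(list(exclusion_threshold = 0.33, family_size = 4,
                              cutoffs = 35:44, initiation_fraction = 0.1),
                         analysis)
  fit <- modifyList(list(n_starts = 5, K_grid = 2:5, fixed = list()), fit)
  structure(list(cohort = cohort, trials_path = trials_path,
                 subjects_path = subjects_path, fit = fit,
                 analysis = analysis, seed = as.integer(seed)),
            class = "rlwm_pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

pair_comparisons <- function(params_tab, g1, g2, family_size) {
  if (!all(c(g1, g2) %in% params_tab$group)) return(NULL)
  a <- params_tab[params_tab$group == g1, ]
  b <- params_tab[params_tab$group == g2, ]
  if (nrow(a) < 3 || nrow(b) < 3) {
    warning(sprintf("too few subjects to compare %s vs %s", g1, g2))
    return(NULL)
  }
  do.call(rbind, lapply(c("alpha", "prior", "epsilon", "phi"), function(p)
    compare_groups(a[[p]], b[[p]], family_size = family_size,
                   label = sprintf("%s vs %s: %s", g1, g2, p))))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load trials; per-subject behavioral summaries and
#' chance-level exclusion; RLWM maximum-likelihood fits; learning curves
#' and logistic growth fits (pooled per group and per subject); group
#' statistics (parameter comparisons with Bonferroni families, age
#' trends, correlation matrices, the age-cutoff classifier, ANOVAs on
#' performance and RT, growth-parameter ANOVA, the rate-ratio identity,
#' speed-accuracy and fit-quality analyses). A stage failure halts with
#' an error naming the stage.
#'
#' @param config an [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV/JSON together with a manifest of content hashes.
#' @return A report bundle (list); see names of the returned object.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rlwm_pipeline_config"))

  data <- stage("data", {
    if (!is.null(config$trials_path)) {
      list(trials = read_trials(config$trials_path),
           subjects = read.csv(config$subjects_path,
                               stringsAsFactors = FALSE),
           simulated = FALSE)
    } else {
      coh <- generate_cohort(config$cohort)
      list(trials = coh$trials, subjects = coh$subjects, simulated = TRUE)
    }
  })

  summaries <- stage("summarize", {
    s <- summarize_cohort(data$trials, data$subjects)
    if (any(table(s$group) < 3))
      warning("some groups have fewer than 3 subjects; ",
              "group tests will be limited")
    s
  })
  excl <- stage("exclude",
                apply_exclusion(summaries, config$analysis$exclusion_threshold))
  kept <- excl$kept
  trials <- data$trials[data$trials$subject_id %in% kept$subject_id, ]

  fits <- stage("fit", {
    ids <- kept$subject_id
    out <- lapply(seq_along(ids), function(i)
      do.call(rlwm_fit,
              c(list(trials = trials[trials$subject_id == ids[i], ],
                     seed = derive_seed(config$seed, i)),
                config$fit)))
    names(out) <- ids
    out
  })
  params_tab <- merge(kept[c("subject_id", "age", "group", "moca",
                             "mean_rt", "accuracy", "ies")],
                      fit_table(fits), by = "subject_id")
  params_tab$prior <- params_tab$rho

  curves <- stage("curves", {
    by_group <- lapply(split(trials, params_tab$group[
      match(trials$subject_id, params_tab$subject_id)]), function(tr)
        compute_learning_curves(tr, by_set_size = TRUE))
    pooled_fit <- lapply(split(trials, params_tab$group[
      match(trials$subject_id, params_tab$subject_id)]), function(tr)
        fit_logistic_growth(compute_learning_curves(tr, by_set_size = FALSE)))
    subject_fits <- lapply(split(trials, trials$subject_id), function(tr)
      fit_logistic_growth(compute_learning_curves(tr, by_set_size = FALSE)))
    subject_fits <- subject_fits[kept$subject_id]
    list(by_group = by_group, pooled_fit = pooled_fit,
         subject_fits = subject_fits)
  })

  analysis <- stage("analyze", {
    fam <- config$analysis$family_size
    comparisons <- rbind(
      pair_comparisons(params_tab, "young", "normal_mid", fam),
      pair_comparisons(params_tab, "normal_mid", "mci_mid", fam))
    trends <- tryCatch(do.call(rbind, lapply(
      c("alpha", "prior", "epsilon", "phi"), function(p)
        age_trend(params_tab[[p]], params_tab$age, label = p))),
      error = function(e) NULL)
    cormat <- tryCatch(parameter_correlation_matrix(params_tab),
                       error = function(e) NULL)
    classifier <- tryCatch(
      logistic_age_classifier(kept, cutoffs = config$analysis$cutoffs,
                              seed = derive_seed(config$seed, 9001)),
      error = function(e) NULL)
    behav_anova <- tryCatch(list(
      rt_by_group = anova_by_factor(params_tab$mean_rt, params_tab$group),
      accuracy_by_group = anova_by_factor(params_tab$accuracy,
                                          params_tab$group)),
      error = function(e) NULL)
    growth_anova <- tryCatch({
      grp <- params_tab$group[match(names(curves$subject_fits),
                                    params_tab$subject_id)]
      compare_growth_parameters(curves$subject_fits, grp)
    }, error = function(e) NULL)
    ratio <- tryCatch({
      y <- params_tab[params_tab$group == "young", ]
      m <- params_tab[params_tab$group == "normal_mid", ]
      ratio_identity(c(mean(y$alpha), mean(m$alpha)),
                     c(mean(y$phi), mean(m$phi)),
                     c(1 / curves$pooled_fit[["young"]]$k,
                       1 / curves$pooled_fit[["normal_mid"]]$k),
                     c(mean(y$mean_rt), mean(m$mean_rt)))
    }, error = function(e) NULL)
    speed_acc <- tryCatch(
      speed_accuracy_analysis(trials, params_tab,
                              config$analysis$initiation_fraction),
      error = function(e) NULL)
    fitq <- tryCatch(
      fit_quality_analysis(fits, params_tab$group[
        match(names(fits), params_tab$subject_id)]),
      error = function(e) NULL)
    list(parameter_comparisons = comparisons, age_trends = trends,
         correlation_matrix = cormat, classifier = classifier,
         behavioral_anova = behav_anova, growth_anova = growth_anova,
         ratio_identity = ratio, speed_accuracy = speed_acc,
         fit_quality = fitq)
  })

  report <- list(config = config, subjects = data$subjects,
                 summaries = summaries, excluded = excl$excluded,
                 fits = fits, parameters = params_tab, curves = curves,
                 analysis = analysis)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) if (!is.null(d) && nrow(d))
    write.csv(d, file.path(out_dir, f), row.names = FALSE, quote = FALSE)
  wcsv(report$summaries, "summaries.csv")
  wcsv(report$excluded, "excluded.csv")
  wcsv(report$parameters, "parameters.csv")
  write_fit_results(report$fits, file.path(out_dir, "fits.jsonl"))
  curves_tab <- do.call(rbind, lapply(names(report$curves$by_group),
    function(g) cbind(group = g, report$curves$by_group[[g]])))
  wcsv(curves_tab, "learning_curves.csv")
  growth_tab <- do.call(rbind, lapply(names(report$curves$pooled_fit),
    function(g) {
      f <- report$curves$pooled_fit[[g]]
      data.frame(group = g, A = f$A, B = f$B, k = f$k, rss = f$rss,
                 degenerate = f$degenerate)
    }))
  wcsv(growth_tab, "growth_fits.csv")
  wcsv(report$analysis$parameter_comparisons, "parameter_comparisons.csv")
  wcsv(report$analysis$age_trends, "age_trends.csv")
  jsonlite::write_json(
    list(seed = report$config$seed,
         n_subjects = nrow(report$summaries),
         n_excluded = nrow(report$excluded),
         classifier_best_cutoff =
           report$analysis$classifier$best_cutoff %||% NA,
         ratio_identity = report$analysis$ratio_identity,
         epsilon_fit_correlation =
           report$analysis$fit_quality$epsilon_fit_correlation),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.csv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(out_dir)
}

#' Miniature deterministic fixture cohort
#'
#' Six subjects (two per group) on a reduced three-block task; small
#' enough to generate in well under a second, used by the unit tests and
#' as a quick demonstration dataset.
#'
#' @param seed master seed.
#' @return An `rlwm_cohort`.
#' @export
make_fixtures <- function(seed = 0L) {
  generate_cohort(cohort_config(
    groups = default_group_specs(2, 2, 2),
    task = task_config(set_sizes = c(2, 3, 4), presentations = 12,
                       training = NULL),
    seed = seed))
}
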