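# Synthetic study cohorts: demographics, cognitive-status labels, group-
# structured RLWM parameters, simulated choice data and reaction times.
# The defaults emulate a 48-subject cross-sectional aging study: 22 young
# adults (18-40), 11 cognitively normal middle-aged adults (41-65) and 15
# middle-aged adults with MCI-range screening scores.
#
# Group parameter locations are underlying normal means (common SD 0.15,
# truncated to [0, 1]); they were calibrated so that the *realized*
# standardized separations between groups match the target effect sizes
# (Cohen's d): young vs normal middle-aged +0.56 alpha, -0.54 phi,
# -0.44 epsilon, 0 rho; normal vs MCI middle-aged -0.53 epsilon only.

PARAM_SD_DEFAULT <- 0.15

GROUP_PARAM_MU <- list(
  young      = c(alpha = 0.2304, phi = 0.1901, rho = 0.8393, epsilon = 0.0722),
  normal_mid = c(alpha = 0.1292, phi = 0.2811, rho = 0.8393, epsilon = 0.1601),
  mci_mid    = c(alpha = 0.1292, phi = 0.2811, rho = 0.8393, epsilon = 0.2525))

# Reaction-time generators: subject mean RT (ms) is linear in the WM
# decay and WM prior weight; the young and middle-aged coefficient sets
# differ, with WM decay weighing far more heavily in middle age.
GROUP_RT_DEFAULTS <- list(
  young      = list(intercept = 600, coef_phi = 722.22, coef_prior = 137.07,
                    noise_sd = 150, error_increment = 120),
  normal_mid = list(intercept = 550, coef_phi = 2355.98, coef_prior = 156.34,
                    noise_sd = 150, error_increment = 120),
  mci_mid    = list(intercept = 800, coef_phi = 2355.98, coef_prior = 156.34,
                    noise_sd = 150, error_increment = 120))

#' Group specification for the synthetic cohort generator
#'
#' @param name one of `"young"`, `"normal_mid"`, `"mci_mid"` (other names
#'   are allowed for custom designs but get no defaults).
#' @param n number of subjects.
#' @param age_range two integers; young groups must lie within 18-40 and
#'   middle-aged groups within 41-65.
#' @param param_mu named vector of underlying normal locations for
#'   `alpha`, `phi`, `rho`, `epsilon` (truncated to \[0, 1\] at draw
#'   time).
#' @param param_sd common SD of the parameter distributions.
#' @param beta,K inverse temperature and WM capacity given to every
#'   subject in the group.
#' @param rt list with `intercept`, `coef_phi`, `coef_prior` (ms and ms
#'   per unit parameter), `noise_sd` (ms) and `error_increment` (ms added
#'   to error trials).
#' @param moca_range two integers; >= 26 for cognitively normal groups,
#'   18-25 for MCI groups.
#' @param age_slope named vector: linear drift of the `phi` and `epsilon`
#'   locations per year of age, centered on the group's mid-range age so
#'   group means are unaffected.
#' @return An object of class `rlwm_group_spec`.
#' @export
group_spec <- function(name, n,
                       age_range = if (name == "young") c(25, 40) else c(41, 65),
                       param_mu = GROUP_PARAM_MU[[name]],
                       param_sd = PARAM_SD_DEFAULT,
                       beta = 8, K = 3L,
                       rt = GROUP_RT_DEFAULTS[[name]],
                       moca_range = if (name == "mci_mid") c(18, 25)
                                    else c(26, 30),
                       age_slope = c(phi = if (name == "young") 0 else 0.004,
                                     epsilon = if (name == "young") 0 else 0.003)) {
  if (is.null(param_mu))
    stopf("no default parameter locations for group '%s'", name)
  stopifnot(is_count(n), n >= 1, length(age_range) == 2,
            length(moca_range) == 2)
  if (!is.numeric(param_sd) || param_sd <= 0)
    stopf("param_sd must be positive")
  if (age_range[1] <= 40 && !(age_range[1] >= 18 && age_range[2] <= 40))
    stopf("young age ranges must lie within [18, 40]")
  if (age_range[1] >= 41 && age_range[2] > 65)
    stopf("middle-aged ranges must lie within [41, 65]")
  if (moca_range[1] >= 26 && moca_range[2] > 30)
    stopf("MoCA scores cannot exceed 30")
  if (moca_range[1] < 26 && !(moca_range[1] >= 18 && moca_range[2] <= 25))
    stopf("MCI-range MoCA scores must lie within [18, 25]")
  structure(list(name = name, n = as.integer(n),
                 age_range = as.integer(age_range),
                 param_mu = param_mu[c("alpha", "phi", "rho", "epsilon")],
                 param_sd = param_sd, beta = beta, K = as.integer(K),
                 rt = rt, moca_range = as.integer(moca_range),
                 age_slope = age_slope),
            class = "rlwm_group_spec")
}

#' Cohort configuration
#'
#' @param groups list of [group_spec()] objects with unique names.
#' @param task an [task_config()].
#' @param seed master seed; every downstream draw derives from it.
#' @export
cohort_config <- function(groups = default_group_specs(), task = task_config(),
                          seed = 11L) {
  nms <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("group names must be unique")
  structure(list(groups = groups, task = task, seed = as.integer(seed)),
            class = "rlwm_cohort_config")
}

#' @rdname cohort_config
#' @param n_young,n_normal_mid,n_mci_mid group sizes; the defaults mirror
#'   a 48-subject study (22 / 11 / 15).
#' @export
default_group_specs <- function(n_young = 22, n_normal_mid = 11,
                                n_mci_mid = 15) {
  list(group_spec("young", n_young),
       group_spec("normal_mid", n_normal_mid),
       group_spec("mci_mid", n_mci_mid))
}

#' Draw one subject's demographics and parameters
#'
#' Consumes the current RNG stream (seed with [set.seed()] or let
#' [generate_cohort()] manage seeding). Age is uniform over the group
#' range; parameters are truncated-normal draws around the group
#' locations, with the configured per-year drift of `phi` and `epsilon`
#' applied relative to the mid-range age; the MoCA score is uniform over
#' the group's score range.
#'
#' @param spec a [group_spec()].
#' @return A list with `age`, `moca` and `params` (an [rlwm_params()]).
#' @export
sample_subject <- function(spec) {
  stopifnot(inherits(spec, "rlwm_group_spec"))
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1)
  moca <- sample(seq(spec$moca_range[1], spec$moca_range[2]), 1)
  mu <- spec$param_mu
  dage <- age - mean(spec$age_range)
  mu["phi"] <- mu["phi"] + spec$age_slope[["phi"]] * dage
  mu["epsilon"] <- mu["epsilon"] + spec$age_slope[["epsilon"]] * dage
  draws <- rtruncnorm01(4, mu, spec$param_sd)
  list(age = age, moca = moca,
       params = rlwm_params(draws[1], draws[2], draws[3], draws[4],
                            beta = spec$beta, K = spec$K))
}

#' Attach reaction times to simulated trials
#'
#' The subject's mean RT is `intercept + coef_phi * phi + coef_prior *
#' rho`; each trial adds the error increment on incorrect trials and
#' Gaussian noise, and the result is clipped to (0, response window\].
#' Consumes the current RNG stream.
#'
#' @param params the subject's [rlwm_params()].
#' @param spec the subject's [group_spec()].
#' @param trials the subject's simulated trial log.
#' @param response_window_ms clipping ceiling in ms.
#' @return Numeric vector of reaction times (ms), one per trial.
#' @export
generate_reaction_times <- function(params, spec, trials,
                                    response_window_ms = 7000) {
  subject_mean <- spec$rt$intercept + spec$rt$coef_phi * params$phi +
    spec$rt$coef_prior * params$rho
  rt <- subject_mean +
    spec$rt$error_increment * (1 - trials$reward) +
    rnorm(nrow(trials), 0, spec$rt$noise_sd)
  round(pmin(pmax(rt, 1), response_window_ms), 3)
}

#' Generate a complete synthetic cohort
#'
#' For every subject: draw demographics and parameters, build a
#' subject-specific task schedule, simulate the agent's choices, attach
#' reaction times, and record the generating truth. Fully reproducible
#' from the configuration's master seed.
#'
#' @param config an [cohort_config()].
#' @return An object of class `rlwm_cohort`: `subjects` (demographics +
#'   generating parameters), `trials` (combined trial log) and the
#'   config.
#' @examples
#' cfg <- cohort_config(default_group_specs(2, 2, 2),
#'                      task_config(set_sizes = c(2, 3), training = NULL))
#' coh <- generate_cohort(cfg)
#' table(coh$subjects$group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rlwm_cohort_config"))
  idx <- 0L
  subjects <- NULL
  trials <- vector("list", sum(vapply(config$groups, `[[`, 1L, "n")))
  for (spec in config$groups) {
    for (j in seq_len(spec$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", spec$name, j)
      s <- derive_seed(config$seed, idx)
      subj <- with_seed(s, sample_subject(spec))
      sched <- generate_schedule(config$task, seed = derive_seed(s, 1))
      tr <- simulate_agent(subj$params, sched, seed = derive_seed(s, 2),
                           subject_id = sid)
      tr$rt_ms <- with_seed(derive_seed(s, 3),
                            generate_reaction_times(
                              subj$params, spec, tr,
                              config$task$response_window * 1000))
      trials[[idx]] <- tr
      subjects <- rbind(subjects, data.frame(
        subject_id = sid, age = subj$age, group = spec$name,
        moca = subj$moca, alpha = subj$params$alpha, phi = subj$params$phi,
        rho = subj$params$rho, epsilon = subj$params$epsilon,
        beta = subj$params$beta, K = subj$params$K,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(subjects = subjects, trials = do.call(rbind, trials),
                 config = config),
            class = "rlwm_cohort")
}

#' @export
print.rlwm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic RLWM cohort: %d subjects (%s), %d trials\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `trials.csv` (trial-log dialect), `subjects.csv`
#' (`subject_id,age,group,moca`) and `cohort_config.json` (provenance
#' echo of group specs and seeds) under `dir`.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  write.csv(cohort$subjects[c("subject_id", "age", "group", "moca")],
            file.path(dir, "subjects.csv"), row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  echo <- list(seed = cfg$seed,
               task = unclass(cfg$task),
               groups = lapply(cfg$groups, unclass),
               note = paste("within-group parameter SDs are generator",
                            "constants, not estimates"))
  jsonlite::write_json(echo, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
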