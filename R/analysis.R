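# Behavioral summaries and the group-level statistical battery:
# chance-level exclusion, normality-gated two-sample comparisons, age
# trends (Spearman + linear regression, reported together because they
# can disagree), parameter correlation matrices, a logistic age-cutoff
# classifier, one-way ANOVA with Tukey HSD, and the speed-accuracy
# analysis (correct vs. error reaction times, inverse efficiency score).

#' Per-subject behavioral summary
#'
#' Accuracy and mean reaction time, overall and per set size, computed
#' over valid learning-block trials, plus the inverse efficiency score
#' (mean RT divided by proportion correct).
#'
#' @param trials one subject's trial-log data frame.
#' @return A one-row data frame with `subject_id`, `accuracy`,
#'   `acc2`..`acc5`, `mean_rt`, `rt2`..`rt5`, `ies`, `n_valid`.
#' @export
summarize_subject <- function(trials) {
  tr <- learning_trials(trials)
  if (nrow(tr) == 0) stopf("subject has no valid learning trials")
  acc <- mean(tr$reward)
  mrt <- mean(tr$rt_ms)
  by_ns <- function(fun, col) vapply(2:5, function(ns) {
    d <- tr[tr$set_size == ns, col]
    if (length(d)) fun(d) else NA_real_
  }, 0)
  accs <- by_ns(mean, "reward")
  rts <- by_ns(mean, "rt_ms")
  out <- data.frame(subject_id = trials$subject_id[1], accuracy = acc,
                    mean_rt = mrt,
                    ies = if (acc > 0) mrt / acc else NA_real_,
                    n_valid = nrow(tr), stringsAsFactors = FALSE)
  out[paste0("acc", 2:5)] <- as.list(accs)
  out[paste0("rt", 2:5)] <- as.list(rts)
  out
}

#' Summaries for every subject in a combined trial log
#'
#' @param trials combined trial log (many subjects).
#' @param subjects optional demographics data frame (`subject_id`, `age`,
#'   `group`, `moca`) merged into the result.
#' @export
summarize_cohort <- function(trials, subjects = NULL) {
  out <- do.call(rbind, lapply(split(trials, trials$subject_id),
                               summarize_subject))
  rownames(out) <- NULL
  if (!is.null(subjects))
    out <- merge(subjects[intersect(names(subjects),
                                    c("subject_id", "age", "group", "moca"))],
                 out, by = "subject_id", sort = TRUE)
  out
}

#' Chance-level performance exclusion
#'
#' Subjects with overall accuracy strictly below the threshold are
#' excluded as performing at chance level; a subject exactly at the
#' threshold is kept.
#'
#' @param summaries output of [summarize_cohort()].
#' @param threshold accuracy cutoff (default 0.33).
#' @return List with `kept` and `excluded` data frames; `excluded` gains
#'   a `reason` column.
#' @export
apply_exclusion <- function(summaries, threshold = 0.33) {
  drop <- summaries$accuracy < threshold
  excluded <- summaries[drop, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("accuracy %.3f below %.2f",
                               excluded$accuracy, threshold)
  list(kept = summaries[!drop, , drop = FALSE], excluded = excluded)
}

cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  d <- mean(a) - mean(b)
  if (!is.finite(sp) || sp == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sp
}

shapiro_p_safe <- function(x) {
  if (length(unique(x)) < 3) return(0) # constant-ish: clearly non-normal
  shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each group; if either deviates from normality
#' (p < 0.05) the groups are compared with the Mann-Whitney U test,
#' otherwise with Welch's t-test. Cohen's d is always reported, and the
#' p-value is Bonferroni-adjusted for the declared family size.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param family_size number of tests in the Bonferroni family this
#'   comparison belongs to.
#' @param label optional comparison label carried into the report.
#' @return One-row data frame: test used, statistic, raw p, adjusted p,
#'   family size, Cohen's d, group sizes, Shapiro p-values.
#' @export
compare_groups <- function(a, b, family_size = 1, label = "") {
  if (length(a) < 3 || length(b) < 3)
    stopf("each group needs at least 3 observations")
  sw_a <- shapiro_p_safe(a)
  sw_b <- shapiro_p_safe(b)
  if (min(sw_a, sw_b) < 0.05) {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    test <- "mann-whitney"
  } else {
    ht <- t.test(a, b)
    test <- "welch"
  }
  p <- ht$p.value
  data.frame(label = label, test = test, statistic = unname(ht$statistic),
             p = p, p_adj = min(1, p * family_size),
             family_size = family_size, cohens_d = cohens_d(a, b),
             n1 = length(a), n2 = length(b),
             shapiro_p1 = sw_a, shapiro_p2 = sw_b,
             stringsAsFactors = FALSE)
}

#' Age trend of a metric: Spearman and linear regression together
#'
#' The two analyses answer different questions (monotone association vs.
#' linear predictability) and can disagree, so both are reported.
#'
#' @param values numeric metric values.
#' @param ages ages (same length, n >= 4).
#' @param label subset label carried into the report.
#' @return One-row data frame with `spearman_rho`, `spearman_p`,
#'   `r_squared`, `regression_p`, `slope` and `n`.
#' @export
age_trend <- function(values, ages, label = "") {
  ok <- complete.cases(values, ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 4) stopf("need at least 4 observations")
  sp <- suppressWarnings(cor.test(values, ages, method = "spearman"))
  fit <- lm(values ~ ages)
  sm <- summary(fit)
  fp <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  data.frame(label = label, spearman_rho = unname(sp$estimate),
             spearman_p = sp$p.value, r_squared = sm$r.squared,
             regression_p = unname(fp), slope = unname(coef(fit)[2]),
             n = length(values), stringsAsFactors = FALSE)
}

#' Pairwise parameter correlation matrices
#'
#' Pearson correlation coefficients and p-values over the four analysis
#' parameters (`alpha`, `prior`, `epsilon`, `phi`); both matrices are
#' reported rather than conflated.
#'
#' @param fits a list of [rlwm_fit()] objects, or a data frame with
#'   columns `alpha`, `rho` (or `prior`), `epsilon`, `phi` (>= 4 rows).
#' @return List of two 4x4 matrices, `r` and `p`, with unit/zero
#'   diagonals respectively.
#' @export
parameter_correlation_matrix <- function(fits) {
  tab <- if (is.data.frame(fits)) fits else fit_table(fits)
  if (!"prior" %in% names(tab)) tab$prior <- tab$rho
  cols <- c("alpha", "prior", "epsilon", "phi")
  if (!all(cols %in% names(tab)))
    stopf("need columns %s", paste(cols, collapse = ", "))
  if (nrow(tab) < 4) stopf("need at least 4 fits")
  m <- as.matrix(tab[cols])
  r <- diag(1, 4); p <- matrix(0, 4, 4)
  dimnames(r) <- dimnames(p) <- list(cols, cols)
  for (i in 1:3) for (j in (i + 1):4) {
    if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
      r[i, j] <- r[j, i] <- NA; p[i, j] <- p[j, i] <- NA
    } else {
      ct <- cor.test(m[, i], m[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Logistic age-cutoff classifier
#'
#' For each candidate cutoff, labels subjects as aged if their age
#' exceeds it, fits a logistic regression of that label on the
#' per-set-size reaction times and accuracies (RT2..RT5,
#' Correct2..Correct5) on a seeded stratified train split, and scores
#' accuracy on the held-out test split. Cutoffs leaving either class
#' empty are skipped and flagged.
#'
#' @param summaries data frame from [summarize_cohort()] with an `age`
#'   column.
#' @param cutoffs integer candidate age cutoffs.
#' @param train_fraction stratified train share.
#' @param seed split seed.
#' @return List with `table` (cutoff, test accuracy, class sizes,
#'   skipped flag) and `best_cutoff` (highest test accuracy).
#' @export
logistic_age_classifier <- function(summaries, cutoffs = 35:44,
                                    train_fraction = 0.75, seed = 1L) {
  feats <- c(paste0("rt", 2:5), paste0("acc", 2:5))
  if (!all(c(feats, "age") %in% names(summaries)))
    stopf("summaries need age plus per-set-size RT and accuracy columns")
  dat <- summaries[complete.cases(summaries[c(feats, "age")]), ]
  rows <- lapply(cutoffs, function(co) {
    y <- as.integer(dat$age > co)
    if (length(unique(y)) < 2)
      return(data.frame(cutoff = co, accuracy = NA_real_,
                        n_train = 0L, n_test = 0L, skipped = TRUE))
    idx <- with_seed(derive_seed(seed, co), {
      unlist(lapply(split(seq_len(nrow(dat)), y), function(ii)
        sample(ii, max(1, floor(train_fraction * length(ii))))))
    })
    train <- dat[idx, ]; test <- dat[-idx, ]
    if (nrow(test) == 0 || length(unique(y[idx])) < 2)
      return(data.frame(cutoff = co, accuracy = NA_real_,
                        n_train = nrow(train), n_test = nrow(test),
                        skipped = TRUE))
    fml <- stats::as.formula(paste("aged ~", paste(feats, collapse = " + ")))
    train$aged <- y[idx]
    fit <- suppressWarnings(glm(fml, family = binomial(), data = train))
    pred <- as.integer(
      suppressWarnings(predict(fit, test, type = "response")) > 0.5)
    data.frame(cutoff = co, accuracy = mean(pred == y[-idx]),
               n_train = nrow(train), n_test = nrow(test), skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!tab$skipped)
  list(table = tab,
       best_cutoff = if (length(ok)) tab$cutoff[ok[which.max(tab$accuracy[ok])]]
                     else NA_integer_)
}

#' One-way ANOVA with Tukey HSD
#'
#' @param values numeric response.
#' @param labels factor-like grouping (>= 2 levels, each n >= 2).
#' @param family_size Bonferroni family for the adjusted alpha reported
#'   alongside.
#' @return List: `F`, `p`, `tukey` (pairwise mean differences with
#'   adjusted p), `alpha_bonferroni`, and `zero_variance` flag (F is
#'   `NaN` when every group is constant).
#' @export
anova_by_factor <- function(values, labels, family_size = 1) {
  g <- factor(as.character(labels))
  cnt <- table(g)
  if (length(cnt) < 2) stopf("need at least 2 factor levels")
  if (any(cnt < 2))
    stopf("level '%s' has fewer than 2 observations", names(cnt)[cnt < 2][1])
  dat <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  zero_var <- all(vapply(split(values, g), function(v) var(v) == 0, TRUE))
  tk <- TukeyHSD(fit)$g
  list(F = if (zero_var) NaN else an[["F value"]][1],
       p = if (zero_var) NaN else an[["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       alpha_bonferroni = 0.05 / family_size,
       zero_variance = zero_var)
}

#' Speed-accuracy analysis
#'
#' Per group: mean reaction time on correct versus error trials, over all
#' valid learning trials and again restricted to post-initiation trials
#' (iterations at or beyond the group learning curve's
#' [learning_initiation()] index); and a regression of per-subject
#' accuracy on per-subject mean RT.
#'
#' @param trials combined trial log.
#' @param subjects data frame mapping `subject_id` to `group`.
#' @param initiation_fraction threshold fraction for the initiation
#'   index.
#' @return List with `rt_by_outcome` (group x phase table of correct and
#'   error mean RTs), `regressions` (per-group accuracy ~ mean RT with
#'   r-squared and p) and `initiation` (per-group index).
#' @export
speed_accuracy_analysis <- function(trials, subjects,
                                    initiation_fraction = 0.1) {
  tr <- learning_trials(trials)
  tr <- merge(tr, subjects[c("subject_id", "group")], by = "subject_id")
  groups <- sort(unique(tr$group))
  init <- setNames(vapply(groups, function(g) {
    cv <- compute_learning_curves(tr[tr$group == g, ], by_set_size = FALSE)
    learning_initiation(fit_logistic_growth(cv),
                        fraction = initiation_fraction)
  }, 0L), groups)
  phase_row <- function(d, g, phase) {
    data.frame(group = g, phase = phase,
               mean_rt_correct = mean(d$rt_ms[d$reward == 1]),
               mean_rt_error = mean(d$rt_ms[d$reward == 0]),
               diff = mean(d$rt_ms[d$reward == 0]) -
                 mean(d$rt_ms[d$reward == 1]),
               n_correct = sum(d$reward == 1), n_error = sum(d$reward == 0),
               stringsAsFactors = FALSE)
  }
  rt_by_outcome <- do.call(rbind, lapply(groups, function(g) {
    d <- tr[tr$group == g, ]
    all_phase <- phase_row(d, g, "all")
    post <- if (is.na(init[[g]])) d[0, ] else d[d$iteration >= init[[g]], ]
    rbind(all_phase,
          if (nrow(post)) phase_row(post, g, "post_initiation"))
  }))
  regressions <- do.call(rbind, lapply(groups, function(g) {
    d <- tr[tr$group == g, ]
    per_subj <- aggregate(cbind(reward, rt_ms) ~ subject_id, data = d, mean)
    if (nrow(per_subj) < 4)
      return(data.frame(group = g, slope = NA_real_, r_squared = NA_real_,
                        p = NA_real_, n = nrow(per_subj)))
    sm <- summary(lm(reward ~ rt_ms, data = per_subj))
    fp <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
    data.frame(group = g, slope = sm$coefficients["rt_ms", "Estimate"],
               r_squared = sm$r.squared, p = unname(fp), n = nrow(per_subj),
               stringsAsFactors = FALSE)
  }))
  list(rt_by_outcome = rt_by_outcome, regressions = regressions,
       initiation = init)
}

#' Reaction-time regression on WM parameters
#'
#' Linear regression of per-subject mean reaction time on the WM decay
#' (`phi`) and WM prior weight (`rho`), the generative structure of the
#' cohort reaction-time model.
#'
#' @param mean_rt per-subject mean RT (ms).
#' @param phi,rho per-subject parameter values.
#' @return List with the coefficient table (estimate, SE, t, p),
#'   r-squared and n.
#' @export
rt_parameter_regression <- function(mean_rt, phi, rho) {
  fit <- lm(mean_rt ~ phi + rho)
  sm <- summary(fit)
  list(coefficients = sm$coefficients, r_squared = sm$r.squared,
       n = length(mean_rt))
}
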