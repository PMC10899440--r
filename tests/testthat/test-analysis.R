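test_that("subject summaries match hand-computed accuracy, RT and IES", {
  tr <- toy_trials(action = c(0L, 0L, 1L, 0L, 1L, 1L),
                   correct = c(0L, 0L, 0L, 0L, 0L, 1L),
                   stimulus = rep(c("s1", "s2"), 3), rt = 600)
  s <- summarize_subject(tr)
  expect_equal(s$accuracy, 4 / 6)
  expect_equal(s$ies, 900)
  expect_equal(s$acc2, 4 / 6)
  expect_true(is.na(s$acc3))

  s2 <- summarize_subject(toy_trials(action = c(0L, 0L, 1L, 1L),
                                     correct = c(0L, 0L, 0L, 0L),
                                     stimulus = rep(c("s1", "s2"), 2),
                                     rt = 600))
  expect_equal(s2$ies, 600 / 0.5)

  # per-set-size accuracies equal hand counts on a 2-block log
  b1 <- toy_trials(action = c(0L, 1L), correct = c(0L, 0L),
                   stimulus = c("s1", "s2"), block = 1L, set_size = 2L)
  b2 <- toy_trials(action = c(2L, 2L, 2L), correct = c(2L, 0L, 1L),
                   stimulus = c("t1", "t2", "t3"), block = 2L, set_size = 3L)
  b2$trial <- b2$trial + 2L
  s3 <- summarize_subject(rbind(b1, b2))
  expect_equal(s3$acc2, 0.5)
  expect_equal(s3$acc3, 1 / 3)
})

test_that("chance-level exclusion uses a strict 33% boundary", {
  mk <- function(acc) data.frame(subject_id = paste0("s", acc),
                                 accuracy = acc)
  res <- apply_exclusion(rbind(mk(0.32), mk(0.33), mk(0.34)))
  expect_equal(nrow(res$excluded), 1)
  expect_match(res$excluded$reason, "below")
  expect_equal(res$kept$accuracy, c(0.33, 0.34))
})

test_that("group comparison gates on normality and reports effect size", {
  # identical samples: maximal p, zero effect
  x <- c(1, 2, 3, 4, 5, 6)
  res <- compare_groups(x, x)
  expect_equal(res$p, 1, tolerance = 1e-9)
  expect_equal(res$cohens_d, 0)
  # complete separation is significant under either branch
  res2 <- compare_groups(1:20, 101:120)
  expect_lt(res2$p, 0.001)
  # heavily skewed data routes to the Mann-Whitney branch
  set.seed(2)
  res3 <- compare_groups(rexp(30)^3, rexp(30)^3)
  expect_equal(res3$test, "mann-whitney")
  set.seed(3)
  res4 <- compare_groups(rnorm(30), rnorm(30))
  expect_equal(res4$test, "welch")
  expect_gte(res4$p_adj, res4$p)
  expect_error(compare_groups(1:2, 1:10), "at least 3")
})

test_that("group comparison detects a configured effect at nominal power", {
  set.seed(11)
  hits <- vapply(1:200, function(i) {
    a <- rnorm(30, 0, 1)
    b <- rnorm(30, 0.8, 1)
    compare_groups(a, b)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("age trends report Spearman and regression side by side", {
  ages <- 20:59
  tr <- suppressWarnings(age_trend(ages, ages)) # perfect fit warns in lm
  expect_equal(tr$spearman_rho, 1)
  expect_equal(tr$r_squared, 1)
  set.seed(4)
  tr2 <- age_trend(rnorm(40), ages)
  expect_gt(tr2$spearman_p, 0.05)
  expect_lt(abs(tr2$spearman_rho), 0.35)
  set.seed(5)
  tr3 <- suppressWarnings(age_trend(-ages + rnorm(40, 0, 1e-6), ages))
  expect_equal(tr3$spearman_rho, -1)
  expect_error(age_trend(1:3, 1:3), "at least 4")
})

test_that("parameter correlation matrices are structural and calibrated", {
  set.seed(6)
  tab <- data.frame(alpha = rnorm(1000), prior = rnorm(1000),
                    epsilon = rnorm(1000), phi = rnorm(1000))
  m <- parameter_correlation_matrix(tab)
  expect_equal(diag(m$r), rep(1, 4), ignore_attr = TRUE)
  expect_identical(m$r, t(m$r))
  expect_true(all(abs(m$r[upper.tri(m$r)]) < 0.1))
  tab$phi <- 2 * tab$alpha + 1 # perfectly correlated pair
  m2 <- parameter_correlation_matrix(tab)
  expect_equal(m2$r["alpha", "phi"], 1)
  expect_error(parameter_correlation_matrix(tab[1:3, ]), "at least 4")
})

test_that("the age classifier finds a separable cutoff and stays honest", {
  mk_summ <- function(ages, jump_at = NULL) {
    n <- length(ages)
    base <- if (is.null(jump_at)) rep(700, n) else
      700 + 400 * (ages > jump_at)
    out <- data.frame(subject_id = sprintf("s%03d", seq_len(n)), age = ages)
    for (k in 2:5) out[[paste0("rt", k)]] <- base + k
    for (k in 2:5) out[[paste0("acc", k)]] <- 0.8 - 0.01 * k
    out
  }
  ages <- rep(36:45, each = 20) # dense coverage of every candidate cutoff
  res <- logistic_age_classifier(mk_summ(ages, jump_at = 40), seed = 3)
  expect_equal(res$best_cutoff, 40)
  expect_equal(res$table$accuracy[res$table$cutoff == 40], 1.0)
  # a cutoff below the youngest age leaves one class empty and is skipped
  expect_true(res$table$skipped[res$table$cutoff == 35])
  # uninformative features: no cutoff reaches perfect held-out accuracy
  set.seed(8)
  summ <- mk_summ(ages)
  for (k in 2:5) summ[[paste0("rt", k)]] <- rnorm(200, 700, 50)
  res2 <- logistic_age_classifier(summ, seed = 3)
  expect_lt(mean(res2$table$accuracy, na.rm = TRUE), 0.9)
  # determinism under the split seed
  expect_identical(res2$table,
                   logistic_age_classifier(summ, seed = 3)$table)
})

test_that("one-way ANOVA with Tukey HSD matches its arithmetic identities", {
  res <- anova_by_factor(rep(c(1, 1, 1), each = 4),
                         rep(c("a", "b", "c"), each = 4))
  expect_true(res$zero_variance)
  expect_true(is.nan(res$F) || !is.finite(res$F))
  set.seed(9)
  y <- c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 2))
  g <- rep(c("a", "b", "c"), each = 30)
  res2 <- anova_by_factor(y, g, family_size = 4)
  expect_lt(res2$p, 0.001)
  expect_equal(res2$alpha_bonferroni, 0.0125)
  means <- tapply(y, g, mean)
  db_a <- res2$tukey$diff[res2$tukey$contrast == "b-a"]
  expect_equal(db_a, unname(means["b"] - means["a"]), tolerance = 1e-12)
  expect_error(anova_by_factor(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2")
})

test_that("speed-accuracy analysis reflects the generating RT structure", {
  specs <- list(
    group_spec("young", 4, rt = list(intercept = 700, coef_phi = 722.22,
                                     coef_prior = 137.07, noise_sd = 20,
                                     error_increment = 200)),
    group_spec("normal_mid", 4, rt = list(intercept = 900,
                                          coef_phi = 2355.98,
                                          coef_prior = 156.34, noise_sd = 20,
                                          error_increment = 200)))
  coh <- generate_cohort(cohort_config(specs, task = tiny_config(c(2, 3), 13),
                                       seed = 3))
  res <- speed_accuracy_analysis(coh$trials, coh$subjects)
  all_rows <- res$rt_by_outcome[res$rt_by_outcome$phase == "all", ]
  expect_true(all(all_rows$diff > 0))
  post <- res$rt_by_outcome[res$rt_by_outcome$phase == "post_initiation", ]
  for (g in post$group) {
    expect_lte(post$n_correct[post$group == g] + post$n_error[post$group == g],
               all_rows$n_correct[all_rows$group == g] +
                 all_rows$n_error[all_rows$group == g])
  }

  # symmetric noise, no increment: outcome difference within 3 SE of zero
  specs0 <- list(group_spec("young", 6,
                            rt = list(intercept = 800, coef_phi = 722.22,
                                      coef_prior = 137.07, noise_sd = 100,
                                      error_increment = 0)))
  coh0 <- generate_cohort(cohort_config(specs0, task = tiny_config(c(2, 3), 13),
                                        seed = 4))
  tr0 <- coh0$trials
  a <- tr0$rt_ms[tr0$reward == 0]
  b <- tr0$rt_ms[tr0$reward == 1]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})
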