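test_that("uniform-noise likelihood equals the analytic value", {
  sched <- generate_schedule(tiny_config(), seed = 1)
  p1 <- rlwm_params(0.4, 0.2, 0.7, 1, beta = 3)
  tr <- simulate_agent(p1, sched, seed = 2)
  got <- rlwm_nll(p1, tr)
  expect_equal(got$nll, got$n_trials * log(3), tolerance = 1e-9)
  # the noise floor keeps probabilities strictly positive
  p2 <- rlwm_params(0.4, 0.2, 0.7, 0.15, beta = 30)
  pr <- rlwm_nll(p2, tr)$p_choice
  expect_true(all(pr >= 0.15 / 3 & pr <= 1))
})

test_that("likelihood reproduces an independently hand-worked sequence", {
  # ns = 2; s1 chosen a0 rewarded, s1 chosen a0 rewarded, s2 chosen a1
  # unrewarded; alpha=.5 phi=0 rho=.5 eps=0 beta=2 K=3. Expected NLL
  # computed step by step with plain arithmetic outside the package.
  tr <- toy_trials(action = c(0L, 0L, 1L), correct = c(0L, 0L, 0L),
                   stimulus = c("s1", "s1", "s2"))
  p <- rlwm_params(0.5, 0, 0.5, 0, beta = 2, K = 3)
  expect_equal(rlwm_nll(p, tr)$nll, 2.7521973377, tolerance = 1e-9)
})

test_that("likelihood skips invalid trials in sum and state", {
  tr <- toy_trials(action = c(0L, 1L, 0L, 0L), correct = c(0L, 0L, 0L, 0L),
                   stimulus = c("s1", "s1", "s1", "s2"))
  p <- rlwm_params(0.5, 0.1, 0.8, 0.1, beta = 5)
  tr_cut <- tr
  tr_cut$valid[2] <- FALSE
  tr_cut$action[2] <- NA_integer_
  tr_cut$reward[2] <- NA_integer_
  got <- rlwm_nll(p, tr_cut)
  expect_equal(got$n_trials, 3)
  expect_true(is.na(got$p_choice[2]))
  # equivalent to the log with that trial deleted outright
  expect_equal(got$nll, rlwm_nll(p, tr[-2, ])$nll, tolerance = 1e-12)
  expect_error(rlwm_nll(p, tr[0, ]), "no trials")
})

test_that("fitting is deterministic and respects likelihood nesting", {
  sched <- generate_schedule(tiny_config(), seed = 3)
  truth <- rlwm_params(0.2, 0.25, 0.85, 0.1)
  tr <- simulate_agent(truth, sched, seed = 4)
  f1 <- rlwm_fit(tr, n_starts = 3, fixed = list(beta = 8, K = 3), seed = 1)
  f2 <- rlwm_fit(tr, n_starts = 3, fixed = list(beta = 8, K = 3), seed = 1)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$nll, f2$nll)
  # optimization can only improve on any directly evaluated candidate
  expect_lte(f1$nll, rlwm_nll(truth, tr)$nll + 1e-9)
  set.seed(11)
  for (i in 1:5) {
    cand <- rlwm_params(runif(1), runif(1), runif(1), runif(1), beta = 8)
    expect_lte(f1$nll, rlwm_nll(cand, tr)$nll + 1e-9)
  }
  expect_s3_class(f1, "rlwm_fit")
  expect_equal(as.numeric(logLik(f1)), -f1$nll)
  expect_length(fitted(f1), nrow(tr))
})

test_that("the uniform model is nested in the fit", {
  sched <- generate_schedule(tiny_config(), seed = 6)
  tr <- simulate_agent(rlwm_params(0.3, 0.2, 0.6, 1), sched, seed = 7)
  f <- rlwm_fit(tr, n_starts = 4, fixed = list(beta = 8, K = 3), seed = 2)
  expect_lte(f$nll, f$n_trials * log(3) + 1e-6)
})

test_that("simulate method regenerates data on the fitted schedule", {
  sched <- generate_schedule(tiny_config(), seed = 8)
  tr <- simulate_agent(rlwm_params(0.2, 0.2, 0.9, 0.1), sched, seed = 9)
  f <- rlwm_fit(tr, n_starts = 2, fixed = list(beta = 8, K = 3), seed = 3)
  sims <- simulate(f, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(tr))
  expect_identical(sims[[1]]$stimulus, tr[order(tr$block, tr$trial), ]$stimulus)
  expect_identical(simulate(f, 1, seed = 5)[[1]], sims[[1]])
})

test_that("recovery report keeps bookkeeping rows and is deterministic", {
  r <- parameter_recovery(2, config = tiny_config(), seed = 21,
                          fit_args = list(n_starts = 2))
  expect_equal(nrow(r$subjects), 2)
  expect_equal(nrow(r$stats), 4)
  r2 <- parameter_recovery(2, config = tiny_config(), seed = 21,
                           fit_args = list(n_starts = 2))
  expect_identical(r$subjects, r2$subjects)
  expect_error(parameter_recovery(1), "n_subjects")
})

test_that("recovery is better identified with more blocks", {
  sampler <- function(i)
    rlwm_params(runif(1, 0.05, 0.6), runif(1, 0, 0.8),
                runif(1, 0.5, 1), runif(1, 0, 0.4), beta = 8, K = 3)
  r10 <- parameter_recovery(60, param_sampler = sampler, seed = 31,
                            fit_args = list(n_starts = 4))
  r2 <- parameter_recovery(60, param_sampler = sampler, seed = 31,
                           config = tiny_config(c(3, 4), 13),
                           fit_args = list(n_starts = 4))
  for (p in c("phi", "epsilon")) {
    c10 <- r10$stats$cor[r10$stats$parameter == p]
    c2 <- r2$stats$cor[r2$stats$parameter == p]
    expect_lt(c2, c10)
  }
})

test_that("fit-quality analysis links noise to attainable likelihood", {
  sched <- generate_schedule(tiny_config(), seed = 41)
  low <- lapply(1:3, function(i)
    rlwm_fit(simulate_agent(rlwm_params(0.2, 0.2, 0.9, 0.05), sched,
                            seed = i, subject_id = paste0("lo", i)),
             n_starts = 2, fixed = list(beta = 8, K = 3), seed = i))
  high <- lapply(1:3, function(i)
    rlwm_fit(simulate_agent(rlwm_params(0.2, 0.2, 0.9, 0.7), sched,
                            seed = 10 + i, subject_id = paste0("hi", i)),
             n_starts = 2, fixed = list(beta = 8, K = 3), seed = i))
  fq <- fit_quality_analysis(c(low, high), rep(c("low", "high"), each = 3))
  tabm <- tapply(fq$table$nll_per_trial, fq$table$group, mean)
  expect_gt(tabm[["high"]], tabm[["low"]])
  expect_false(fq$epsilon_fit_correlation$undefined)
  # both sign conventions are reported and mirror each other
  expect_equal(fq$epsilon_fit_correlation$estimate_vs_nll,
               -fq$epsilon_fit_correlation$estimate_vs_loglik)

  # identical groups: degenerate t = 0
  same <- c(low, low)
  fq2 <- fit_quality_analysis(same, rep(c("a", "b"), each = 3))
  expect_equal(fq2$group_nll_tests$t, 0)
  expect_equal(fq2$group_nll_tests$p, 1)
  expect_error(fit_quality_analysis(low[1:2], c("a", "b")), "3 fits")
})

test_that("fit results serialize to the documented JSON schema", {
  sched <- generate_schedule(tiny_config(), seed = 51)
  tr <- simulate_agent(rlwm_params(0.2, 0.2, 0.9, 0.1), sched, seed = 52,
                       subject_id = "sX")
  f <- rlwm_fit(tr, n_starts = 2, fixed = list(beta = 8, K = 3), seed = 1)
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_setequal(names(js), c("subject_id", "params", "nll", "n_trials",
                               "n_starts", "converged", "seed"))
  expect_equal(js$params$alpha, f$params$alpha)
  path <- tempfile(fileext = ".jsonl")
  write_fit_results(list(f, f), path)
  expect_length(readLines(path), 2)
  tab <- fit_table(list(f))
  expect_equal(tab$subject_id, "sX")
})
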