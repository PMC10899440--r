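test_that("WM mixture weight follows the capacity scaling", {
  expect_equal(wm_weight(1.0, 5, 2), 1.0)
  expect_equal(wm_weight(0.8, 3, 5), 0.48)
  expect_equal(wm_weight(0.0, 3, 2), 0.0)
  expect_error(wm_weight(0.5, 3, 0), "set size")
})

test_that("softmax policy matches direct evaluation and is stable", {
  expect_equal(softmax_policy(c(1, 1, 1) / 3, 7), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(1, 0, 0), 0), rep(1 / 3, 3))
  # frozen from a direct high-precision evaluation of exp(b*q)/sum
  expect_equal(softmax_policy(c(0.5, 0.3, 0.2), 5),
               c(0.6285317, 0.2312239, 0.1402444), tolerance = 1e-6)
  # max-subtraction keeps extreme temperatures finite
  p <- softmax_policy(c(1, 0, 0), 5000)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(softmax_policy(c(NaN, 0, 0), 1), "finite")
})

test_that("policy mixing and undirected noise follow the mixture form", {
  u <- rep(1 / 3, 3)
  expect_equal(mix_and_noise(c(.9, .05, .05), c(.1, .5, .4), 0.7, 1), u)
  expect_equal(mix_and_noise(u, c(.2, .5, .3), 0, 0), c(.2, .5, .3))
  expect_equal(mix_and_noise(c(0.8, 0.1, 0.1), c(0.4, 0.3, 0.3), 0.5, 0.1),
               c(43, 16, 16) / 75, tolerance = 1e-12)
  expect_error(mix_and_noise(c(0.5, 0.4, 0.4), u, 0.5, 0), "distribution")
})

test_that("delta-rule and WM updates behave at the boundary cases", {
  expect_equal(rl_update(1 / 3, 1, 0.1), 0.4)
  expect_equal(rl_update(0.5, 0, 1.0), 0.0)
  expect_equal(rl_update(0.7, 1, 0), 0.7)

  st <- agent_state(c("a", "b"))
  expect_true(all(st$Q_wm == 1 / 3))
  st1 <- wm_store(st, "a", 1L, 1)
  expect_equal(st1$Q_wm["a", 2], 1)
  expect_equal(st1$Q_wm["b", ], st$Q_wm["b", ])
  expect_identical(wm_store(st1, "a", 1L, 1), st1) # idempotent
  expect_error(wm_store(st, "zz", 0L, 1), "not part")

  expect_identical(wm_decay_step(st1, 0), st1)
  st2 <- wm_decay_step(st1, 1)
  expect_equal(unname(st2$Q_wm), matrix(1 / 3, 2, 3), tolerance = 1e-15)
  st3 <- wm_decay_step(st1, 0.5)
  expect_equal(st3$Q_wm["a", 2], 2 / 3)
})

test_that("trial choice probabilities compose the mixture policy", {
  p <- rlwm_params(0.3, 0.2, 0.9, 0.05, beta = 4, K = 3)
  st <- agent_state(c("a", "b", "c"))
  expect_equal(unname(trial_choice_probabilities(st, p, "a")), rep(1 / 3, 3))
  p_noise <- rlwm_params(0.3, 0.2, 0.9, 1, beta = 4, K = 3)
  st_l <- rlwm_step(st, p, "a", 0L, 1)
  expect_equal(unname(trial_choice_probabilities(st_l, p_noise, "a")), rep(1 / 3, 3))
  # one rewarded trial with perfect WM pins the next choice
  pp <- rlwm_params(0.1, 0, 1, 0, beta = 100, K = 5)
  st2 <- rlwm_step(agent_state(c("a", "b", "c")), pp, "a", 2L, 1)
  expect_gt(trial_choice_probabilities(st2, pp, "a")[3], 0.999)
})

test_that("compiled engine agrees with the R primitive composition", {
  set.seed(42)
  for (i in 1:4) {
    params <- rlwm_params(runif(1), runif(1), runif(1), runif(1) * 0.6,
                          beta = runif(1, 1, 20), K = sample(2:5, 1))
    sched <- generate_schedule(tiny_config(c(2, 4)), seed = i)
    tr <- simulate_agent(params, sched, seed = 100 + i,
                         return_policy = TRUE)
    ref <- reference_policy(params, tr)
    expect_equal(unname(attr(tr, "policy")), unname(ref), tolerance = 1e-12)
    got <- rlwm_nll(params, tr)
    expect_equal(got$nll, reference_nll(params, tr), tolerance = 1e-10)
    # emitted distributions are proper
    expect_true(all(abs(rowSums(ref) - 1) < 1e-12))
    expect_true(all(ref >= 0))
  }
})

test_that("value tables stay within their bounds over long histories", {
  set.seed(7)
  params <- rlwm_params(runif(1), runif(1), runif(1), runif(1), beta = 6)
  sched <- generate_schedule(tiny_config(c(3, 5), 14), seed = 2)
  tr <- simulate_agent(params, sched, seed = 3)
  for (blk in unique(tr$block)) {
    rows <- which(tr$block == blk)
    st <- agent_state(unique(tr$stimulus[rows]))
    for (i in rows) {
      st <- rlwm_step(st, params, tr$stimulus[i], tr$action[i], tr$reward[i])
      expect_true(all(st$Q_wm >= 0 & st$Q_wm <= 1))
      expect_true(all(st$Q_rl >= 0 & st$Q_rl <= 1))
    }
  }
})

test_that("simulation is deterministic and hits its analytic limits", {
  sched <- generate_schedule(tiny_config(), seed = 1)
  p <- rlwm_params(0.2, 0.3, 0.8, 0.1)
  expect_identical(simulate_agent(p, sched, seed = 5),
                   simulate_agent(p, sched, seed = 5))
  expect_false(identical(simulate_agent(p, sched, seed = 5)$action,
                         simulate_agent(p, sched, seed = 6)$action))

  # pure-noise agents perform at chance
  pn <- rlwm_params(0.2, 0.3, 0.8, 1)
  acc <- vapply(1:200, function(i)
    mean(simulate_agent(pn, sched, seed = i)$reward), 0)
  n_obs <- 200 * nrow(simulate_agent(pn, sched, seed = 1))
  expect_lt(abs(mean(acc) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n_obs))

  # a perfect-WM agent never errs after the first rewarded presentation
  pw <- rlwm_params(0.1, 0, 1, 0, beta = 100, K = 5)
  tr <- simulate_agent(pw, sched, seed = 11)
  for (s in unique(tr$stimulus)) {
    d <- tr[tr$stimulus == s, ]
    first_hit <- match(1L, d$reward)
    if (!is.na(first_hit) && first_hit < nrow(d))
      expect_true(all(d$reward[(first_hit + 1):nrow(d)] == 1))
  }
})

test_that("parameter bounds and JSON serialization are enforced", {
  expect_error(rlwm_params(-0.1, 0, 0, 0), "alpha")
  expect_error(rlwm_params(0, 1.2, 0, 0), "phi")
  expect_error(rlwm_params(0, 0, 0, 0, beta = -1), "beta")
  expect_error(rlwm_params(0, 0, 0, 0, K = 0), "K")
  p <- rlwm_params(0.12, 0.3, 0.9, 0.05, beta = 7.5, K = 4)
  expect_equal(params_from_json(params_to_json(p)), p)
})
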