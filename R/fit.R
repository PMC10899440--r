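# Maximum-likelihood estimation of RLWM parameters from trial logs:
# trial-wise likelihood along the realized history, multi-start bounded
# local optimization (L-BFGS-B) over the continuous parameters with an
# exhaustive scan over the discrete capacity K, plus the standard
# simulate-fit parameter-recovery harness.

rlwm_bounds <- function() {
  list(alpha = c(0, 1), phi = c(0, 1), rho = c(0, 1), epsilon = c(0, 1),
       beta = c(0.1, 50))
}

#' Negative log-likelihood of a trial log under RLWM parameters
#'
#' Replays the subject's realized choices and rewards through the agent
#' state and accumulates `-sum(log p(chosen action))` over valid learning
#' trials. Training-block (block 0) trials are excluded; invalid
#' (timeout) trials contribute neither likelihood nor state updates. The
#' per-trial probability is floored at 1e-12 inside the log only.
#'
#' @param params an [rlwm_params()].
#' @param trials a trial-log data frame.
#' @param include_training include block 0 in the likelihood.
#' @return A list with `nll` (nats), `n_trials` (valid trials entering
#'   the sum) and `p_choice` (per-trial probability of the realized
#'   choice, `NA` for invalid trials).
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' tr <- simulate_agent(rlwm_params(0.1, 0.3, 0.9, 0.05), sched, seed = 2)
#' rlwm_nll(rlwm_params(0.1, 0.3, 0.9, 0.05), tr)$nll
#' @export
rlwm_nll <- function(params, trials, include_training = FALSE) {
  stopifnot(inherits(params, "rlwm_params"))
  if (!include_training) trials <- trials[trials$block != 0, , drop = FALSE]
  if (nrow(trials) == 0) stopf("no trials to evaluate")
  if (any(trials$valid & !(trials$action %in% 0:2)))
    stopf("actions must lie in {0, 1, 2}")
  tr <- engine_inputs(trials)
  pol <- rlwm_policy_cpp(params$alpha, params$phi, params$rho,
                         params$epsilon, params$beta, params$K,
                         tr$block, tr$stim_idx, tr$set_size,
                         ifelse(is.na(tr$action), -1L, tr$action),
                         ifelse(is.na(tr$reward), 0L, tr$reward), tr$valid)
  p <- rep(NA_real_, nrow(tr))
  v <- which(tr$valid)
  p[v] <- pol[cbind(v, tr$action[v] + 1)]
  list(nll = -sum(log(pmax(p[v], 1e-12))), n_trials = length(v),
       p_choice = p)
}

# Fast objective used inside the optimizer (no data-frame overhead).
make_nll_fn <- function(trials) {
  tr <- engine_inputs(trials[trials$block != 0, , drop = FALSE])
  blk <- tr$block; stim <- tr$stim_idx; ns <- tr$set_size
  act <- ifelse(is.na(tr$action), -1L, tr$action)
  rew <- ifelse(is.na(tr$reward), 0L, tr$reward)
  val <- tr$valid
  function(alpha, phi, rho, epsilon, beta, K)
    rlwm_nll_cpp(alpha, phi, rho, epsilon, beta, K,
                 blk, stim, ns, act, rew, val)
}

#' Fit the RLWM model to one subject's trial log
#'
#' Bounded maximum-likelihood estimation: for each capacity value in
#' `K_grid`, `n_starts` L-BFGS-B runs are launched from seeded random
#' initial points within the parameter bounds (`alpha`, `phi`, `rho`,
#' `epsilon` in \[0, 1\], `beta` in \[0.1, 50\]); the best negative
#' log-likelihood over all starts and capacities wins, ties broken by
#' first found. Any parameter (including `K`) can be pinned via `fixed`.
#' Deterministic under a fixed seed.
#'
#' @param trials trial-log data frame for one subject.
#' @param n_starts random starts per capacity value.
#' @param K_grid integer capacities to scan.
#' @param fixed named list of parameters to hold fixed, e.g.
#'   `list(beta = 8, K = 3)`.
#' @param seed integer seed for the start points.
#' @param subject_id identifier; defaults to the log's.
#' @return An object of class `rlwm_fit` with methods [print()],
#'   [summary()], [coef()], [logLik()], [fitted()] (per-trial probability
#'   of the realized choice) and [simulate()].
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' tr <- simulate_agent(rlwm_params(0.15, 0.3, 0.9, 0.1), sched, seed = 2)
#' fit <- rlwm_fit(tr, n_starts = 3, fixed = list(beta = 8, K = 3), seed = 1)
#' coef(fit)
#' @export
rlwm_fit <- function(trials, n_starts = 20, K_grid = 2:5,
                     fixed = list(), seed = 1L, subject_id = NULL) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  subject_id <- subject_id %||% trials$subject_id[1]
  bounds <- rlwm_bounds()
  cont <- names(bounds)
  bad <- setdiff(names(fixed), c(cont, "K"))
  if (length(bad)) stopf("unknown fixed parameter(s): %s",
                         paste(bad, collapse = ", "))
  free <- setdiff(cont, names(fixed))
  if ("K" %in% names(fixed)) K_grid <- as.integer(fixed$K)
  nll_fn <- make_nll_fn(trials)
  n_trials <- sum(trials$valid & trials$block != 0)
  if (n_trials == 0) stopf("no valid learning trials to fit")

  lower <- vapply(bounds[free], `[`, 0, 1)
  upper <- vapply(bounds[free], `[`, 0, 2)
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * length(free)), n_starts)
    colnames(m) <- free
    for (j in seq_along(free)) {
      if (free[j] == "beta") # log-uniform: starts spread over magnitudes
        m[, j] <- exp(log(lower[j]) + m[, j] * (log(upper[j]) - log(lower[j])))
      else
        m[, j] <- lower[j] + m[, j] * (upper[j] - lower[j])
    }
    m
  })

  assemble <- function(theta, K) {
    full <- as.list(fixed)
    full[free] <- as.list(theta)
    full$K <- K
    full
  }
  obj <- function(theta, K) {
    p <- assemble(theta, K)
    v <- nll_fn(p$alpha, p$phi, p$rho, p$epsilon, p$beta %||% 8, p$K)
    if (!is.finite(v)) .Machine$double.xmax else v
  }

  best <- NULL
  diagnostics <- NULL
  for (K in K_grid) {
    for (i in seq_len(nrow(starts))) {
      res <- if (length(free)) {
        tryCatch(
          optim(starts[i, ], obj, K = K, method = "L-BFGS-B",
                lower = lower, upper = upper,
                control = list(maxit = 500)),
          error = function(e) list(par = starts[i, ], value = Inf,
                                   convergence = 99L))
      } else {
        list(par = numeric(0), value = obj(numeric(0), K), convergence = 0L)
      }
      diagnostics <- rbind(diagnostics,
                           data.frame(K = K, start = i, nll = res$value,
                                      convergence = res$convergence))
      if (is.null(best) || res$value < best$value)
        best <- list(par = res$par, value = res$value, K = K,
                     convergence = res$convergence)
    }
  }
  full <- assemble(best$par, best$K)
  params <- rlwm_params(full$alpha, full$phi, full$rho, full$epsilon,
                        full$beta %||% 8, full$K)
  structure(list(subject_id = subject_id, params = params, nll = best$value,
                 n_trials = n_trials, n_starts = n_starts,
                 K_grid = as.integer(K_grid), free = free, fixed = fixed,
                 converged = any(diagnostics$convergence == 0 &
                                   diagnostics$nll <= best$value + 1e-9),
                 diagnostics = diagnostics, seed = as.integer(seed),
                 trials = trials),
            class = "rlwm_fit")
}

#' @export
print.rlwm_fit <- function(x, ...) {
  cat(sprintf("RLWM fit for subject '%s'\n", x$subject_id))
  print(x$params)
  cat(sprintf("  NLL %.3f over %d trials (%.4f nats/trial); %s\n",
              x$nll, x$n_trials, x$nll / x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.rlwm_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
logLik.rlwm_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$free) +
              (length(object$K_grid) > 1), nobs = object$n_trials,
            class = "logLik")
}

#' @export
fitted.rlwm_fit <- function(object, ...) {
  rlwm_nll(object$params, object$trials)$p_choice
}

#' @export
summary.rlwm_fit <- function(object, ...) {
  conv <- table(factor(object$diagnostics$convergence == 0,
                       levels = c(TRUE, FALSE)))
  structure(list(fit = object, nll_per_trial = object$nll / object$n_trials,
                 starts_converged = conv[["TRUE"]],
                 starts_total = nrow(object$diagnostics)),
            class = "summary.rlwm_fit")
}

#' @export
print.summary.rlwm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d/%d optimizer starts converged\n",
              x$starts_converged, x$starts_total))
  invisible(x)
}

#' @export
simulate.rlwm_fit <- function(object, nsim = 1, seed = 1L, ...) {
  tr <- engine_inputs(object$trials)
  p <- object$params
  lapply(seq_len(nsim), function(i) {
    u <- with_seed(derive_seed(seed, i), runif(nrow(tr)))
    sim <- rlwm_sim_cpp(p$alpha, p$phi, p$rho, p$epsilon, p$beta, p$K,
                        tr$block, tr$stim_idx, tr$set_size,
                        tr$correct_action, u, FALSE)
    out <- tr[setdiff(names(tr), "stim_idx")]
    out$action <- sim$action
    out$reward <- sim$reward
    out$rt_ms <- NA_real_
    out$valid <- TRUE
    out
  })
}

#' Export fit results
#'
#' `fit_to_json()` renders one fit as a JSON object with keys
#' `subject_id, params, nll, n_trials, n_starts, converged, seed`;
#' `write_fit_results()` writes a list of fits as JSON lines;
#' `fit_table()` collects the parameter estimates into a data frame.
#'
#' @param fit an `rlwm_fit`.
#' @param fits a list of `rlwm_fit` objects.
#' @param path output file.
#' @export
fit_to_json <- function(fit) {
  jsonlite::toJSON(list(subject_id = fit$subject_id,
                        params = unclass(fit$params), nll = fit$nll,
                        n_trials = fit$n_trials, n_starts = fit$n_starts,
                        converged = fit$converged, seed = fit$seed),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname fit_to_json
#' @export
write_fit_results <- function(fits, path) {
  writeLines(vapply(fits, function(f) as.character(fit_to_json(f)), ""),
             path)
  invisible(path)
}

#' @rdname fit_to_json
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, alpha = f$params$alpha,
               phi = f$params$phi, rho = f$params$rho,
               epsilon = f$params$epsilon, beta = f$params$beta,
               K = f$params$K, nll = f$nll, n_trials = f$n_trials,
               converged = f$converged, stringsAsFactors = FALSE)))
}

#' Simulate-and-refit parameter recovery
#'
#' Draws generating parameters, simulates each synthetic subject on a
#' fresh schedule, refits, and summarizes per-parameter recovery
#' (Pearson correlation, mean bias, RMSE). Fit failures are kept as
#' flagged rows, never dropped.
#'
#' @param n_subjects number of simulated subjects (>= 2).
#' @param param_sampler function of one argument (the subject index RNG
#'   is already seeded) returning an [rlwm_params()]; the default draws
#'   `alpha`, `phi`, `rho`, `epsilon` uniformly in \[0, 1\] with
#'   `beta = 8`, `K = 3`.
#' @param config task configuration for the simulated sessions.
#' @param seed master seed.
#' @param fit_args list of arguments passed on to [rlwm_fit()]; defaults
#'   to `n_starts = 10` with `beta` and `K` held at their generating
#'   values.
#' @return An object of class `rlwm_recovery`: data frame `subjects`
#'   (true and estimated parameters), data frame `stats` (per-parameter
#'   correlation, bias, RMSE) and the configuration used.
#' @export
parameter_recovery <- function(n_subjects, param_sampler = NULL,
                               config = task_config(), seed = 7L,
                               fit_args = list()) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  param_sampler <- param_sampler %||% function(i)
    rlwm_params(runif(1), runif(1), runif(1), runif(1), beta = 8, K = 3L)
  fit_args <- modifyList(list(n_starts = 10, fixed = list(beta = 8, K = 3L)),
                         fit_args)
  rows <- lapply(seq_len(n_subjects), function(i) {
    s_i <- derive_seed(seed, i)
    truth <- with_seed(s_i, param_sampler(i))
    sched <- generate_schedule(config, seed = derive_seed(s_i, 1))
    trials <- simulate_agent(truth, sched, seed = derive_seed(s_i, 2),
                             subject_id = sprintf("rec%03d", i))
    fit <- tryCatch(
      do.call(rlwm_fit, c(list(trials = trials, seed = derive_seed(s_i, 3)),
                          fit_args)),
      error = function(e) NULL)
    data.frame(
      subject = i,
      true_alpha = truth$alpha, true_phi = truth$phi,
      true_rho = truth$rho, true_epsilon = truth$epsilon,
      est_alpha = if (is.null(fit)) NA else fit$params$alpha,
      est_phi = if (is.null(fit)) NA else fit$params$phi,
      est_rho = if (is.null(fit)) NA else fit$params$rho,
      est_epsilon = if (is.null(fit)) NA else fit$params$epsilon,
      nll = if (is.null(fit)) NA else fit$nll,
      failed = is.null(fit) || !fit$converged)
  })
  subjects <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(c("alpha", "phi", "rho", "epsilon"),
    function(p) {
      tr <- subjects[[paste0("true_", p)]]
      es <- subjects[[paste0("est_", p)]]
      ok <- complete.cases(tr, es)
      data.frame(parameter = p,
                 cor = if (sum(ok) > 2) cor(tr[ok], es[ok]) else NA,
                 bias = mean(es[ok] - tr[ok]),
                 rmse = sqrt(mean((es[ok] - tr[ok])^2)),
                 n = sum(ok))
    }))
  structure(list(subjects = subjects, stats = stats, seed = seed,
                 config = config, fit_args = fit_args),
            class = "rlwm_recovery")
}

#' @export
print.rlwm_recovery <- function(x, ...) {
  cat(sprintf("RLWM parameter recovery over %d simulated subjects\n",
              nrow(x$subjects)))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

# Welch t robust to zero-variance degenerate groups.
welch_t_safe <- function(a, b) {
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (!is.finite(se) || se == 0) {
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p.value = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a, b)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       degenerate = FALSE)
}

#' Fit-quality analysis
#'
#' Correlates the fitted undirected-noise parameter with per-subject fit
#' quality and compares normalized negative log-likelihood between
#' labeled groups. Because the sign convention for "correlation with
#' model fit" is ambiguous, the correlation is reported against both the
#' per-trial NLL and the per-trial log-likelihood (its negative).
#'
#' @param fits list of [rlwm_fit()] objects (>= 3).
#' @param group_labels factor-like vector, one label per fit.
#' @return A list with the epsilon-fit correlations (estimate, p) under
#'   both conventions, a per-pair Welch t-test table of per-trial NLL,
#'   and the underlying per-subject table.
#' @export
fit_quality_analysis <- function(fits, group_labels) {
  if (length(fits) < 3) stopf("need at least 3 fits")
  stopifnot(length(group_labels) == length(fits))
  tab <- fit_table(fits)
  tab$group <- as.character(group_labels)
  tab$nll_per_trial <- tab$nll / tab$n_trials
  if (sd(tab$epsilon) == 0) {
    eps_cor <- list(estimate_vs_nll = NA_real_, estimate_vs_loglik = NA_real_,
                    p = NA_real_, undefined = TRUE)
  } else {
    ct <- cor.test(tab$epsilon, tab$nll_per_trial)
    eps_cor <- list(estimate_vs_nll = unname(ct$estimate),
                    estimate_vs_loglik = -unname(ct$estimate),
                    p = ct$p.value, undefined = FALSE)
  }
  groups <- unique(tab$group)
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE)
           else list()
  group_tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- tab$nll_per_trial[tab$group == pr[1]]
    b <- tab$nll_per_trial[tab$group == pr[2]]
    w <- welch_t_safe(a, b)
    data.frame(group1 = pr[1], group2 = pr[2],
               mean1 = mean(a), mean2 = mean(b),
               t = w$statistic, p = w$p.value,
               degenerate = w$degenerate, stringsAsFactors = FALSE)
  }))
  list(epsilon_fit_correlation = eps_cor, group_nll_tests = group_tests,
       table = tab)
}
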