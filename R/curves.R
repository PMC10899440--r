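# Learning curves aligned on the presentation (iteration) index, logistic
# growth fitting P(t) = A / (1 + B * exp(-k t)), learning-initiation
# detection, and group statistics on the growth parameters.

GROWTH_BOUNDS <- list(A = c(1e-6, 1), B = c(1e-6, 1e3), k = c(1e-6, 10))

#' Iteration-aligned learning curves
#'
#' Mean proportion correct at each presentation index, pooled across
#' stimuli, blocks and subjects, optionally split by set size. Each curve
#' is truncated at the minimum per-stimulus presentation count among its
#' contributing stimuli so every cell is balanced. Training-block and
#' invalid trials are excluded.
#'
#' @param trials trial-log data frame (may hold many subjects).
#' @param by_set_size split curves by block set size.
#' @return A data frame of class `rlwm_curves` with columns
#'   `set_size` (`"all"` or the set size), `iteration`, `mean_correct`,
#'   `n` (contributing observations).
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' tr <- simulate_agent(rlwm_params(0.1, 0.2, 0.9, 0.05), sched, seed = 2)
#' head(compute_learning_curves(tr))
#' @export
compute_learning_curves <- function(trials, by_set_size = TRUE) {
  stopifnot(is.data.frame(trials))
  tr <- learning_trials(trials)
  if (nrow(tr) == 0) stopf("no valid learning trials")
  one_curve <- function(d, label) {
    per_stim <- aggregate(iteration ~ subject_id + block + stimulus,
                          data = d, FUN = max)
    t_max <- min(per_stim$iteration)
    d <- d[d$iteration <= t_max, , drop = FALSE]
    ag <- aggregate(reward ~ iteration, data = d,
                    FUN = function(x) c(mean(x), length(x)))
    data.frame(set_size = label, iteration = ag$iteration,
               mean_correct = ag$reward[, 1], n = as.integer(ag$reward[, 2]),
               stringsAsFactors = FALSE)
  }
  out <- if (by_set_size) {
    do.call(rbind, lapply(sort(unique(tr$set_size)), function(ns)
      one_curve(tr[tr$set_size == ns, , drop = FALSE], as.character(ns))))
  } else {
    one_curve(tr, "all")
  }
  class(out) <- c("rlwm_curves", "data.frame")
  out
}

logistic_growth <- function(t, A, B, k) A / (1 + B * exp(-k * t))

#' Fit the logistic growth model to a learning curve
#'
#' Bounded least squares for `P(t) = A / (1 + B * exp(-k t))` with
#' `A` in (0, 1\] (asymptote), `B` in (0, 1e3\] (scaling) and `k` in
#' (0, 10\] (growth rate). Initialization is deterministic: `A` starts at
#' the curve maximum, `k` on a small fixed grid, and `B` is solved from
#' the first point; the best converged run wins, so the fit is a pure
#' function of the data. Curves with no measurable rise are flagged
#' degenerate (with `k` reported at its lower bound) rather than
#' mis-fit.
#'
#' @param curve a data frame with columns `iteration` and `mean_correct`
#'   (e.g. one set-size slice of [compute_learning_curves()]), or a
#'   numeric vector of per-iteration accuracies.
#' @return An object of class `rlwm_growth` with elements `A`, `B`, `k`,
#'   `rss`, `domain`, `degenerate`, `converged`.
#' @examples
#' y <- 0.8 / (1 + 5 * exp(-0.6 * (1:13)))
#' fit <- fit_logistic_growth(y)
#' coef(fit)
#' @export
fit_logistic_growth <- function(curve) {
  if (is.numeric(curve))
    curve <- data.frame(iteration = seq_along(curve), mean_correct = curve)
  stopifnot(all(c("iteration", "mean_correct") %in% names(curve)))
  t <- curve$iteration
  y <- curve$mean_correct
  if (length(t) < 4) stopf("need at least 4 curve points")
  if (any(y < 0 | y > 1)) stopf("curve values must lie in [0, 1]")
  lower <- vapply(GROWTH_BOUNDS, `[`, 0, 1)
  upper <- vapply(GROWTH_BOUNDS, `[`, 0, 2)
  domain <- range(t)

  if (diff(range(y)) < 1e-3) { # flat curve: no growth to fit
    return(structure(list(A = mean(y), B = lower[["B"]], k = lower[["k"]],
                          rss = sum((y - mean(y))^2), domain = domain,
                          degenerate = TRUE, converged = TRUE,
                          curve = curve),
                     class = "rlwm_growth"))
  }

  rss_fn <- function(p) {
    r <- y - logistic_growth(t, p[1], p[2], p[3])
    sum(r * r)
  }
  A0 <- min(max(max(y), 0.05), 1)
  best <- NULL
  for (k0 in c(0.1, 0.3, 0.5, 1, 2)) {
    B0 <- (A0 / max(y[which.min(t)], 0.02) - 1) * exp(k0 * min(t))
    B0 <- min(max(B0, lower[["B"]] * 10), upper[["B"]])
    res <- tryCatch(
      optim(c(A0, B0, k0), rss_fn, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    return(structure(list(A = NA_real_, B = NA_real_, k = NA_real_,
                          rss = NA_real_, domain = domain,
                          degenerate = TRUE, converged = FALSE,
                          curve = curve),
                     class = "rlwm_growth"))
  p <- best$par
  rise <- logistic_growth(domain[2], p[1], p[2], p[3]) -
    logistic_growth(domain[1], p[1], p[2], p[3])
  structure(list(A = p[1], B = p[2], k = p[3], rss = best$value,
                 domain = domain,
                 degenerate = rise < 0.02 || p[3] <= lower[["k"]] * 1.01,
                 converged = best$convergence == 0, curve = curve),
            class = "rlwm_growth")
}

#' @export
coef.rlwm_growth <- function(object, ...) {
  c(A = object$A, B = object$B, k = object$k)
}

#' @export
print.rlwm_growth <- function(x, ...) {
  cat(sprintf(
    "Logistic growth fit: A=%.4f B=%.4f k=%.4f (rss %.3g)%s\n",
    x$A, x$B, x$k, x$rss, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
predict.rlwm_growth <- function(object, t = NULL, ...) {
  t <- t %||% seq(object$domain[1], object$domain[2])
  logistic_growth(t, object$A, object$B, object$k)
}

#' @export
plot.rlwm_growth <- function(x, ...) {
  graphics::plot(x$curve$iteration, x$curve$mean_correct,
                 xlab = "iteration", ylab = "proportion correct",
                 ylim = c(0, 1), pch = 19, ...)
  tt <- seq(x$domain[1], x$domain[2], length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Learning-initiation iteration
#'
#' The smallest integer iteration at which the fitted curve has risen a
#' given fraction of the way from its first-iteration value toward the
#' asymptote: `P(t) >= P(1) + fraction * (A - P(1))` (baseline-normalized
#' rise, the default). `rule = "literal"` instead thresholds the raw
#' curve at `fraction * A`; with typical above-chance baselines this is
#' met at the first iteration, which is why the normalized rule is the
#' default.
#'
#' @param fit an [fit_logistic_growth()] result.
#' @param fraction threshold fraction in (0, 1).
#' @param rule `"normalized"` or `"literal"`.
#' @return Integer iteration, or `NA` if the threshold is never reached
#'   within the fit domain (or the fit is degenerate).
#' @export
learning_initiation <- function(fit, fraction = 0.1,
                                rule = c("normalized", "literal")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "rlwm_growth"), fraction > 0, fraction < 1)
  if (fit$degenerate || !is.finite(fit$A)) return(NA_integer_)
  tt <- seq(fit$domain[1], fit$domain[2])
  p <- predict(fit, tt)
  thr <- if (rule == "normalized") {
    p1 <- p[1]
    if (fit$A <= p1) return(NA_integer_)
    p1 + fraction * (fit$A - p1)
  } else {
    fraction * fit$A
  }
  hit <- which(p >= thr - 1e-12)
  if (!length(hit)) return(NA_integer_)
  as.integer(tt[hit[1]])
}

#' Group comparison of growth parameters
#'
#' One-way ANOVA plus Tukey HSD post-hoc contrasts on the per-subject
#' growth rate `k` and asymptote `A`.
#'
#' @param fits list of [fit_logistic_growth()] results, one per subject.
#' @param group_labels group label per fit (>= 2 groups, >= 2 fits each).
#' @return A list with one entry per parameter (`k`, `A`): ANOVA `F` and
#'   `p`, and the Tukey table of pairwise mean differences with adjusted
#'   p-values; plus the underlying per-subject table.
#' @export
compare_growth_parameters <- function(fits, group_labels) {
  stopifnot(length(fits) == length(group_labels))
  tab <- data.frame(
    k = vapply(fits, `[[`, 0, "k"),
    A = vapply(fits, `[[`, 0, "A"),
    group = factor(as.character(group_labels)))
  cnt <- table(tab$group)
  if (length(cnt) < 2) stopf("need at least 2 groups")
  if (any(cnt < 2))
    stopf("group '%s' has fewer than 2 fits", names(cnt)[cnt < 2][1])
  one <- function(v) {
    fml <- stats::as.formula(paste(v, "~ group"))
    fit <- aov(fml, data = tab)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
         tukey = data.frame(contrast = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            row.names = NULL))
  }
  list(k = one("k"), A = one("A"), table = tab)
}

#' Rate-ratio identity between model parameters and learning speed
#'
#' Compares, for two groups, the ratio of mean RL learning rates divided
#' by the ratio of mean WM decay rates (left-hand side) against the
#' product of the learning-curve time-constant ratio and the mean
#' reaction-time ratio (right-hand side). The two sides are reported with
#' their relative gap; their equality is an empirical observation about a
#' cohort, not an identity that is enforced.
#'
#' @param alpha_means,phi_means length-2 vectors of group mean `alpha`
#'   and `phi` (group 1, group 2).
#' @param tau length-2 vector of learning-curve time constants (e.g.
#'   `1 / k`).
#' @param rt length-2 vector of group mean reaction times.
#' @return List with `lhs`, `rhs` and `relative_gap = |lhs - rhs| / rhs`.
#' @export
ratio_identity <- function(alpha_means, phi_means, tau, rt) {
  for (v in list(alpha_means, phi_means, tau, rt))
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0))
      stopf("all inputs must be positive length-2 vectors")
  lhs <- (alpha_means[1] / alpha_means[2]) / (phi_means[1] / phi_means[2])
  rhs <- (tau[1] / tau[2]) * (rt[1] / rt[2])
  list(lhs = unname(lhs), rhs = unname(rhs),
       relative_gap = unname(abs(lhs - rhs) / rhs))
}
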