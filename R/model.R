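# The RLWM agent: a capacity-limited, instantly-learning but decaying
# working-memory system mixed with a slow delta-rule reinforcement
# learner. Choices follow a weighted mixture of the two softmax policies,
# blurred by undirected (lapse) noise.
#
# The exported step primitives operate on an explicit agent state and are
# the readable reference implementation; simulation and likelihood use a
# compiled loop with identical semantics (cross-checked in the tests).

#' RLWM model parameters
#'
#' @param alpha reinforcement-learning rate, in \[0, 1\].
#' @param phi working-memory decay: per-trial pull of every stored WM
#'   value back toward the uninformative initial value 1/3, in \[0, 1\].
#' @param rho working-memory prior weight: maximum probability mass given
#'   to the WM policy before capacity scaling, in \[0, 1\].
#' @param epsilon undirected decision noise (uniform lapse), in \[0, 1\].
#' @param beta softmax inverse temperature, > 0, shared by both systems.
#' @param K working-memory capacity (items), integer >= 1; enters only
#'   through the mixture weight `rho * min(1, K / ns)`.
#' @return An object of class `rlwm_params` (a named list).
#' @examples
#' p <- rlwm_params(alpha = 0.1, phi = 0.3, rho = 0.9, epsilon = 0.05)
#' @export
rlwm_params <- function(alpha, phi, rho, epsilon, beta = 8, K = 3L) {
  p <- list(alpha = alpha, phi = phi, rho = rho, epsilon = epsilon,
            beta = beta, K = as.integer(K))
  for (nm in c("alpha", "phi", "rho", "epsilon"))
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stopf("%s must lie in [0, 1]", nm)
  if (!is.numeric(beta) || is.na(beta) || beta < 0)
    stopf("beta must be nonnegative")
  if (p$K < 1) stopf("K must be a positive integer")
  structure(p, class = "rlwm_params")
}

#' @export
print.rlwm_params <- function(x, ...) {
  cat(sprintf(
    "RLWM parameters: alpha=%.3f phi=%.3f rho=%.3f epsilon=%.3f beta=%.2f K=%d\n",
    x$alpha, x$phi, x$rho, x$epsilon, x$beta, x$K))
  invisible(x)
}

#' Serialize parameters to/from JSON
#'
#' @param params an [rlwm_params()] object.
#' @param json a JSON string or file path.
#' @export
params_to_json <- function(params) {
  jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  rlwm_params(x$alpha, x$phi, x$rho, x$epsilon, x$beta, x$K)
}

#' Working-memory mixture weight
#'
#' The probability that the working-memory policy governs a choice:
#' `rho * min(1, K / ns)`. When the set size exceeds capacity, the WM
#' contribution is diluted by `K / ns`.
#'
#' @param rho WM prior weight in \[0, 1\].
#' @param K WM capacity, >= 1.
#' @param ns block set size, >= 1.
#' @export
wm_weight <- function(rho, K, ns) {
  if (ns < 1) stopf("set size must be >= 1")
  stopifnot(rho >= 0, rho <= 1, K >= 1)
  rho * min(1, K / ns)
}

#' Softmax action policy
#'
#' `p_i` proportional to `exp(beta * q_i)`, computed with max
#' subtraction so that large `beta` values stay finite.
#'
#' @param q numeric vector of action values.
#' @param beta inverse temperature, >= 0 (0 gives the uniform policy).
#' @export
softmax_policy <- function(q, beta) {
  if (any(!is.finite(q))) stopf("action values must be finite")
  if (!is.finite(beta) || beta < 0) stopf("beta must be >= 0 and finite")
  e <- exp(beta * (q - max(q)))
  e / sum(e)
}

#' Mix system policies and apply undirected noise
#'
#' `pi = p_wm * pi_wm + (1 - p_wm) * pi_rl`, then
#' `pi' = (1 - epsilon) * pi + epsilon / 3`.
#'
#' @param pi_wm,pi_rl valid probability distributions over the 3 actions.
#' @param p_wm WM mixture weight in \[0, 1\].
#' @param epsilon undirected noise in \[0, 1\].
#' @export
mix_and_noise <- function(pi_wm, pi_rl, p_wm, epsilon) {
  for (p in list(pi_wm, pi_rl))
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stopf("policy inputs must be length-3 probability distributions")
  stopifnot(p_wm >= 0, p_wm <= 1, epsilon >= 0, epsilon <= 1)
  mixed <- p_wm * pi_wm + (1 - p_wm) * pi_rl
  (1 - epsilon) * mixed + epsilon / 3
}

#' Delta-rule value update
#'
#' Returns `q + alpha * (r - q)`; the reward prediction error `r - q`
#' drives the update.
#'
#' @param q current action value.
#' @param reward observed reward (0 or 1).
#' @param alpha learning rate in \[0, 1\].
#' @export
rl_update <- function(q, reward, alpha) {
  stopifnot(alpha >= 0, alpha <= 1, reward %in% c(0, 1))
  q + alpha * (reward - q)
}

#' Agent state for one block
#'
#' Both value tables start at the uninformative value `1/3` (one over the
#' number of actions) for every stimulus-action pair.
#'
#' @param stimuli character vector of the block's stimulus identifiers.
#' @return An object of class `rlwm_state` holding `Q_rl` and `Q_wm`
#'   (stimulus-by-action matrices) and the block set size.
#' @export
agent_state <- function(stimuli) {
  ns <- length(stimuli)
  if (ns < 1) stopf("a block needs at least one stimulus")
  q <- matrix(1 / 3, ns, 3, dimnames = list(stimuli, ACTION_LABELS))
  structure(list(Q_rl = q, Q_wm = q, set_size = ns), class = "rlwm_state")
}

check_stimulus <- function(state, stimulus) {
  if (!stimulus %in% rownames(state$Q_wm))
    stopf("stimulus '%s' is not part of the current block", stimulus)
}

#' Working-memory one-shot storage
#'
#' WM learns with rate 1: the stored value becomes the observed reward
#' exactly; all other entries are untouched.
#'
#' @param state an [agent_state()].
#' @param stimulus stimulus identifier.
#' @param action chosen action (0, 1 or 2).
#' @param reward observed reward (0 or 1).
#' @export
wm_store <- function(state, stimulus, action, reward) {
  check_stimulus(state, stimulus)
  stopifnot(action %in% 0:2, reward %in% c(0, 1))
  state$Q_wm[stimulus, action + 1] <- reward
  state
}

#' Working-memory decay step
#'
#' Every WM entry relaxes toward the initial value:
#' `Q_wm <- Q_wm + phi * (1/3 - Q_wm)`.
#'
#' @param state an [agent_state()].
#' @param phi decay rate in \[0, 1\].
#' @export
wm_decay_step <- function(state, phi) {
  stopifnot(phi >= 0, phi <= 1)
  state$Q_wm <- state$Q_wm + phi * (1 / 3 - state$Q_wm)
  state
}

#' Choice probabilities for one trial
#'
#' Softmax policies over the stimulus's WM and RL value rows (shared
#' `beta`), mixed with the capacity-scaled WM weight and blurred by the
#' undirected noise.
#'
#' @param state an [agent_state()].
#' @param params an [rlwm_params()].
#' @param stimulus stimulus identifier within the current block.
#' @export
trial_choice_probabilities <- function(state, params, stimulus) {
  check_stimulus(state, stimulus)
  p_wm <- wm_weight(params$rho, params$K, state$set_size)
  mix_and_noise(softmax_policy(state$Q_wm[stimulus, ], params$beta),
                softmax_policy(state$Q_rl[stimulus, ], params$beta),
                p_wm, params$epsilon)
}

#' Apply one trial's feedback to the agent state
#'
#' Delta-rule RL update of the chosen entry, one-shot WM storage, then
#' decay of every WM entry — the post-feedback update order used
#' throughout the package.
#'
#' @inheritParams wm_store
#' @param params an [rlwm_params()].
#' @export
rlwm_step <- function(state, params, stimulus, action, reward) {
  check_stimulus(state, stimulus)
  state$Q_rl[stimulus, action + 1] <-
    rl_update(state$Q_rl[stimulus, action + 1], reward, params$alpha)
  state <- wm_store(state, stimulus, action, reward)
  wm_decay_step(state, params$phi)
}

# Order trials and derive the 0-based per-block stimulus index expected
# by the compiled engine.
engine_inputs <- function(trials) {
  trials <- trials[order(trials$block, trials$trial), , drop = FALSE]
  trials$stim_idx <- stats::ave(
    as.integer(factor(trials$stimulus)), trials$block,
    FUN = function(v) match(v, unique(v)) - 1L)
  trials
}

#' Simulate an RLWM agent on a schedule
#'
#' Runs the agent generatively: each trial's choice is sampled from the
#' model policy along the agent's own history, reward is 1 exactly when
#' the choice matches the schedule's correct action, and the state is
#' reset at every block start. Deterministic given `(params, schedule,
#' seed)`.
#'
#' @param params an [rlwm_params()].
#' @param schedule an [generate_schedule()] result.
#' @param seed integer seed for the choice randomness.
#' @param subject_id identifier written into the trial log.
#' @param return_policy if `TRUE`, the per-trial policy matrix is
#'   attached as attribute `"policy"`.
#' @return A trial-log data frame (one row per scheduled trial, internal
#'   action coding, `rt_ms = NA`, all trials valid).
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' trials <- simulate_agent(rlwm_params(0.1, 0.3, 0.9, 0.05), sched, seed = 2)
#' mean(trials$reward[trials$block != 0])
#' @export
simulate_agent <- function(params, schedule, seed = 1L, subject_id = "sim",
                           return_policy = FALSE) {
  stopifnot(inherits(params, "rlwm_params"),
            inherits(schedule, "rlwm_schedule"))
  fr <- schedule_frame(schedule)
  u <- with_seed(seed, runif(nrow(fr)))
  sim <- rlwm_sim_cpp(params$alpha, params$phi, params$rho, params$epsilon,
                      params$beta, params$K,
                      fr$block, fr$stim_idx, fr$set_size, fr$correct_action,
                      u, isTRUE(return_policy))
  out <- data.frame(subject_id = subject_id, block = fr$block,
                    trial = fr$trial, set_size = fr$set_size,
                    stimulus = fr$stimulus, iteration = fr$iteration,
                    action = sim$action, correct_action = fr$correct_action,
                    reward = sim$reward, rt_ms = NA_real_, valid = TRUE,
                    stringsAsFactors = FALSE)
  if (isTRUE(return_policy)) attr(out, "policy") <- sim$policy
  out
}
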