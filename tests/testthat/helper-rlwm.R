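# Shared fixtures and a pure-R reference forward pass, built from the
# exported step primitives so the compiled engine can be checked against
# an independent composition path.

tiny_config <- function(set_sizes = c(2, 3), presentations = 12)
  task_config(set_sizes = set_sizes, presentations = presentations,
              training = NULL)

# Hand-buildable trial rows (internal coding).
toy_trials <- function(action, correct, block = 1L, set_size = 2L,
                       stimulus = NULL, rt = NA_real_, subject = "toy") {
  n <- length(action)
  stimulus <- stimulus %||% rep("s1", n)
  iter <- stats::ave(seq_len(n), stimulus, FUN = seq_along)
  data.frame(subject_id = subject, block = block, trial = seq_len(n),
             set_size = set_size, stimulus = stimulus,
             iteration = as.integer(iter), action = as.integer(action),
             correct_action = as.integer(correct),
             reward = as.integer(action == correct),
             rt_ms = rt, valid = TRUE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference per-trial policy along a realized history, composed from the
# exported R step primitives (no compiled code).
reference_policy <- function(params, trials) {
  trials <- trials[trials$block != 0, , drop = FALSE]
  out <- matrix(NA_real_, nrow(trials), 3)
  for (blk in unique(trials$block)) {
    rows <- which(trials$block == blk)
    state <- agent_state(unique(trials$stimulus[rows]))
    for (i in rows) {
      out[i, ] <- trial_choice_probabilities(state, params,
                                             trials$stimulus[i])
      if (trials$valid[i])
        state <- rlwm_step(state, params, trials$stimulus[i],
                           trials$action[i], trials$reward[i])
    }
  }
  out
}

reference_nll <- function(params, trials) {
  trials <- trials[trials$block != 0 & trials$valid, , drop = FALSE]
  pol <- reference_policy(params, trials)
  -sum(log(pol[cbind(seq_len(nrow(trials)), trials$action + 1)]))
}
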