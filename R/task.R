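# Task design: schedule generation and trial-log I/O.
#
# A session is one optional training block (block 0) followed by
# `n_learning_blocks` learning blocks. Each block shows a fresh set of
# ns stimuli, each presented 12-14 times in a pseudo-randomly interleaved
# order; the subject responds with one of three keys (J/K/L, coded 0/1/2
# in memory) within the response window and receives deterministic
# correct/incorrect feedback.

ACTION_LABELS <- c("J", "K", "L")

TRIAL_COLUMNS <- c("subject_id", "block", "trial", "set_size", "stimulus",
                   "iteration", "action", "correct_action", "reward",
                   "rt_ms", "valid")

#' Task configuration
#'
#' Describes the block structure of the stimulus-action association task:
#' per-block set sizes (2-5 stimuli), per-stimulus presentation counts
#' (12-14), the three-key response set, and the interleaving constraint.
#' The default is a 10-learning-block session plus a 36-trial training
#' block, totalling 468 trials.
#'
#' @param set_sizes integer vector, one set size per learning block, each
#'   in 2..5.
#' @param presentations per-stimulus presentation count, scalar or one per
#'   block, each in 12..14.
#' @param n_actions number of response keys; the model assumes 3.
#' @param response_window response deadline in seconds.
#' @param max_run_length maximum number of consecutive presentations of
#'   the same stimulus tolerated by the interleaver.
#' @param training `NULL` for no training block, or a list with elements
#'   `set_size` and `presentations`.
#' @return An object of class `rlwm_task_config`.
#' @examples
#' cfg <- task_config()
#' total_trials(cfg)
#' @export
task_config <- function(set_sizes = c(2, 3, 4, 5, 2, 3, 4, 5, 3, 4),
                        presentations = c(12, 12, 13, 12, 12, 12, 12, 13, 13, 12),
                        n_actions = 3,
                        response_window = 7,
                        max_run_length = 3,
                        training = list(set_size = 3, presentations = 12)) {
  set_sizes <- as.integer(set_sizes)
  if (any(set_sizes < 2 | set_sizes > 5))
    stopf("all set sizes must lie in [2, 5]")
  if (length(presentations) == 1)
    presentations <- rep(presentations, length(set_sizes))
  presentations <- as.integer(presentations)
  if (length(presentations) != length(set_sizes))
    stopf("presentations must be scalar or one per block")
  if (any(presentations < 12 | presentations > 14))
    stopf("presentation counts must lie in [12, 14]")
  if (n_actions != 3)
    stopf("the model is defined for exactly 3 actions")
  if (!is.null(training)) {
    if (!all(c("set_size", "presentations") %in% names(training)))
      stopf("training block spec needs set_size and presentations")
  }
  structure(list(set_sizes = set_sizes, presentations = presentations,
                 n_actions = 3L, response_window = response_window,
                 max_run_length = as.integer(max_run_length),
                 training = training),
            class = "rlwm_task_config")
}

#' @rdname task_config
#' @param config an `rlwm_task_config`.
#' @export
total_trials <- function(config) {
  n <- sum(config$set_sizes * config$presentations)
  if (!is.null(config$training))
    n <- n + config$training$set_size * config$training$presentations
  as.integer(n)
}

# Interleave `counts[i]` copies of stimulus i so that no stimulus repeats
# more than max_run times in a row; seeded shuffle with rejection.
interleave_stimuli <- function(counts, max_run, max_tries = 2000L) {
  if (length(counts) == 1 && counts[1] > max_run)
    stopf("interleaving infeasible: one stimulus cannot satisfy max_run_length")
  pool <- rep(seq_along(counts), counts)
  for (i in seq_len(max_tries)) {
    seq_i <- sample(pool)
    r <- rle(seq_i)
    if (max(r$lengths) <= max_run) return(seq_i)
  }
  stopf("interleaving failed after %d tries (max_run_length = %d)",
        max_tries, max_run)
}

#' Generate a task schedule
#'
#' Draws, for every block, a fresh set of stimulus identifiers, a random
#' stimulus-to-correct-action map, and a pseudo-randomly interleaved
#' presentation sequence. The same `(config, seed)` pair always yields the
#' identical schedule. The training block, when present, is block 0;
#' learning blocks are numbered from 1.
#'
#' @param config an [task_config()] object.
#' @param seed integer seed controlling all schedule randomness.
#' @return An object of class `rlwm_schedule`: a list with the config,
#'   the seed, and one entry per block carrying `block`, `set_size`,
#'   `training`, `stimuli`, `correct_action` (named 0/1/2 vector) and
#'   `sequence` (indices into `stimuli`).
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' length(sched$blocks)
#' @export
generate_schedule <- function(config, seed = 1L) {
  stopifnot(inherits(config, "rlwm_task_config"))
  with_seed(seed, {
    specs <- data.frame(set_size = config$set_sizes,
                        presentations = config$presentations,
                        block = seq_along(config$set_sizes),
                        training = FALSE)
    if (!is.null(config$training))
      specs <- rbind(data.frame(set_size = config$training$set_size,
                                presentations = config$training$presentations,
                                block = 0L, training = TRUE),
                     specs)
    blocks <- lapply(seq_len(nrow(specs)), function(i) {
      ns <- specs$set_size[i]
      stimuli <- sprintf("b%02d_s%d", specs$block[i], seq_len(ns))
      correct <- setNames(sample(0:2, ns, replace = TRUE), stimuli)
      seq_i <- interleave_stimuli(rep(specs$presentations[i], ns),
                                  config$max_run_length)
      list(block = specs$block[i], set_size = ns,
           training = specs$training[i], stimuli = stimuli,
           correct_action = correct, sequence = seq_i)
    })
    structure(list(config = config, seed = as.integer(seed), blocks = blocks),
              class = "rlwm_schedule")
  })
}

#' @export
print.rlwm_schedule <- function(x, ...) {
  nb <- sum(!vapply(x$blocks, `[[`, TRUE, "training"))
  cat(sprintf("RLWM task schedule: %d learning block(s)%s, %d trials, seed %d\n",
              nb,
              if (any(vapply(x$blocks, `[[`, TRUE, "training")))
                " + training" else "",
              sum(vapply(x$blocks, function(b) length(b$sequence), 1L)),
              x$seed))
  invisible(x)
}

# Expand a schedule into one row per trial (no choices yet).
schedule_frame <- function(schedule) {
  do.call(rbind, lapply(schedule$blocks, function(b) {
    n <- length(b$sequence)
    stim <- b$stimuli[b$sequence]
    iter <- stats::ave(seq_len(n), b$sequence, FUN = seq_along)
    data.frame(block = b$block, trial = seq_len(n), set_size = b$set_size,
               stimulus = stim, stim_idx = b$sequence - 1L,
               iteration = as.integer(iter),
               correct_action = unname(b$correct_action[stim]),
               training = b$training)
  }))
}

#' Export a schedule to JSON
#'
#' @param schedule an `rlwm_schedule`.
#' @param path file to write; when `NULL` the JSON string is returned.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  payload <- list(
    seed = schedule$seed,
    blocks = lapply(schedule$blocks, function(b)
      list(block = b$block, set_size = b$set_size, training = b$training,
           stimuli = b$stimuli,
           correct_action = as.list(b$correct_action),
           sequence = b$sequence)))
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write trial logs
#'
#' Trial logs are UTF-8 CSV files with the fixed column set
#' `subject_id,block,trial,set_size,stimulus,iteration,action,correct_action,reward,rt_ms,valid`.
#' Actions are stored as the key labels J/K/L and mapped to the internal
#' 0/1/2 coding on read; invalid (timeout) trials carry empty action,
#' reward and reaction-time fields. `read_trials()` enforces the log
#' invariants (reward equals 1 exactly when the chosen action matches the
#' correct action; iterations start at 1) and reports the offending row
#' number on failure.
#'
#' @param trials data frame of trial records (internal coding).
#' @param path CSV file path.
#' @return `read_trials()` returns the trials data frame in internal
#'   coding; `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  out <- trials[intersect(TRIAL_COLUMNS, names(trials))]
  missing <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing))
    stopf("trials lack column(s): %s", paste(missing, collapse = ", "))
  out <- out[TRIAL_COLUMNS]
  out$action <- ifelse(is.na(out$action), "", ACTION_LABELS[out$action + 1])
  out$correct_action <- ACTION_LABELS[out$correct_action + 1]
  out$reward <- ifelse(is.na(out$reward), "", out$reward)
  out$valid <- ifelse(out$valid, "true", "false")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(sort(names(raw)), sort(TRIAL_COLUMNS)))
    stopf("unexpected trial-log columns: %s",
          paste(names(raw), collapse = ","))
  raw <- raw[TRIAL_COLUMNS]
  n <- nrow(raw)
  decode_action <- function(x, what) {
    a <- match(x, ACTION_LABELS) - 1L
    bad <- which(!is.na(x) & x != "" & is.na(a))
    if (length(bad))
      stopf("row %d: unrecognized %s '%s'", bad[1], what, x[bad[1]])
    a
  }
  out <- data.frame(
    subject_id = raw$subject_id,
    block = as.integer(raw$block),
    trial = as.integer(raw$trial),
    set_size = as.integer(raw$set_size),
    stimulus = raw$stimulus,
    iteration = as.integer(raw$iteration),
    action = decode_action(raw$action, "action"),
    correct_action = decode_action(raw$correct_action, "correct action"),
    reward = suppressWarnings(as.integer(raw$reward)),
    rt_ms = suppressWarnings(as.numeric(raw$rt_ms)),
    valid = raw$valid %in% c("true", "TRUE", "1"),
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  if (any(is.na(out$correct_action)))
    stopf("row %d: missing correct action",
          which(is.na(out$correct_action))[1])
  v <- which(out$valid)
  bad <- v[is.na(out$action[v]) | is.na(out$reward[v])]
  if (length(bad))
    stopf("row %d: valid trial lacks action or reward", bad[1])
  bad <- v[out$reward[v] != as.integer(out$action[v] == out$correct_action[v])]
  if (length(bad))
    stopf("row %d: reward inconsistent with action/correct action", bad[1])
  if (any(out$iteration < 1))
    stopf("row %d: iteration must start at 1", which(out$iteration < 1)[1])
  out
}

# Drop training-block and invalid trials; the default analysis set.
learning_trials <- function(trials, keep_invalid = FALSE) {
  out <- trials[trials$block != 0, , drop = FALSE]
  if (!keep_invalid) out <- out[out$valid, , drop = FALSE]
  out
}
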