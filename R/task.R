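#' Transition structure of the two-step task
#'
#' The first-stage actions (0 and 1) lead probabilistically to one of two
#' second-stage states. Action `a`'s *common* state is state `a`; with
#' probability `1 - common_prob` the transition is *rare* and the agent lands
#' in the other state. The default 0.7 reproduces the standard 70/30 design.
#'
#' @param common_prob probability of the common transition, in (0.5, 1).
#' @return an object of class `transition_structure`.
#' @export
transition_structure <- function(common_prob = 0.7) {
  if (!is.numeric(common_prob) || length(common_prob) != 1 ||
      common_prob <= 0.5 || common_prob >= 1) {
    stopf("common_prob must be a single number in (0.5, 1), got %s",
          format(common_prob))
  }
  structure(list(common_prob = common_prob, common_state = c(0L, 1L)),
            class = "transition_structure")
}

#' Task configuration
#'
#' Bundles the session length, the tutorial block sizes and the reward-walk
#' settings. The default session has 200 scored trials preceded by a
#' 50-trial tutorial (10 response-training, 20 second-stage-only, 20 full
#' practice trials); practice data never enter any analysis.
#'
#' @param n_trials number of scored trials per session.
#' @param n_practice_response,n_practice_stage2,n_practice_full tutorial
#'   block sizes.
#' @param step_sd per-trial standard deviation of the Gaussian reward walks
#'   (probability units).
#' @param bounds length-2 reflecting bounds for the walks, inside `[0, 1]`.
#' @param common_prob probability of the common transition.
#' @param counterbalance_id integer selecting one of the walk-column
#'   permutations used to counterbalance reward walks across participants.
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 200L, n_practice_response = 10L,
                        n_practice_stage2 = 20L, n_practice_full = 20L,
                        step_sd = 0.025, bounds = c(0.25, 0.75),
                        common_prob = 0.7, counterbalance_id = 1L) {
  if (n_trials <= 0) stopf("n_trials must be positive")
  if (length(bounds) != 2 || bounds[1] >= bounds[2] ||
      bounds[1] < 0 || bounds[2] > 1) {
    stopf("bounds must be an increasing pair inside [0, 1]")
  }
  if (step_sd < 0) stopf("step_sd must be non-negative")
  structure(list(
    n_trials = as.integer(n_trials),
    n_practice_response = as.integer(n_practice_response),
    n_practice_stage2 = as.integer(n_practice_stage2),
    n_practice_full = as.integer(n_practice_full),
    step_sd = step_sd, bounds = bounds,
    structure = transition_structure(common_prob),
    counterbalance_id = as.integer(counterbalance_id)
  ), class = "task_config")
}

#' Tutorial schedule implied by a task configuration
#'
#' @param config a [task_config()].
#' @return a data.frame with one row per tutorial block and its trial count.
#' @export
practice_schedule <- function(config = task_config()) {
  data.frame(
    block = c("response_training", "stage2_only", "full_practice"),
    n_trials = c(config$n_practice_response, config$n_practice_stage2,
                 config$n_practice_full),
    stringsAsFactors = FALSE
  )
}

#' Generate the four Gaussian reward-probability walks
#'
#' Each of the four second-stage options (2 states x 2 options) carries a
#' reward probability that drifts by independent Gaussian steps and reflects
#' off the bounds, forcing continual learning. Initial values are drawn
#' uniformly within the bounds.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same seed yields an identical walk set.
#' @return an object of class `reward_walks`: a list with `probs`
#'   (`n_trials` x 4 matrix, columns state0/optA, state0/optB, state1/optA,
#'   state1/optB), `step_sd`, `bounds` and `seed`.
#' @export
generate_reward_walks <- function(config = task_config(), seed = 1L) {
  lo <- config$bounds[1]; hi <- config$bounds[2]
  n <- config$n_trials
  probs <- withr_seed(seed, {
    m <- matrix(NA_real_, n, 4)
    m[1, ] <- runif(4, lo, hi)
    if (n > 1) {
      steps <- matrix(rnorm((n - 1) * 4, 0, config$step_sd), n - 1, 4)
      for (t in 2:n) m[t, ] <- reflect(m[t - 1, ] + steps[t - 1, ], lo, hi)
    }
    m
  })
  colnames(probs) <- c("s0_a", "s0_b", "s1_a", "s1_b")
  structure(list(probs = probs, step_sd = config$step_sd,
                 bounds = config$bounds, seed = as.integer(seed)),
            class = "reward_walks")
}

# reflect values into [lo, hi] (repeatedly, for steps larger than the range)
reflect <- function(x, lo, hi) {
  for (i in seq_len(20)) {
    over <- x > hi; x[over] <- 2 * hi - x[over]
    under <- x < lo; x[under] <- 2 * lo - x[under]
    if (!any(x > hi | x < lo)) break
  }
  x
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Counterbalance a walk set
#'
#' Reward walks are counterbalanced across participants by permuting which
#' option carries which trajectory: the eight mappings combine swapping the
#' two options within each state and swapping the two states' walk pairs.
#' `counterbalance_id` is taken modulo 8 and assigned round-robin across a
#' cohort; a participant keeps the same mapping at follow-up.
#'
#' @param walks a [generate_reward_walks()] result.
#' @param counterbalance_id non-negative integer.
#' @return a `reward_walks` object with permuted columns.
#' @export
counterbalance_walks <- function(walks, counterbalance_id = 1L) {
  id <- as.integer(counterbalance_id) %% 8L
  cols <- 1:4
  if (id %% 2L == 1L) cols <- cols[c(2, 1, 3, 4)]      # swap options, state 0
  if ((id %/% 2L) %% 2L == 1L) cols <- cols[c(1, 2, 4, 3)]  # state 1
  if ((id %/% 4L) %% 2L == 1L) cols <- cols[c(3, 4, 1, 2)]  # swap states
  out <- walks
  out$probs <- walks$probs[, cols, drop = FALSE]
  colnames(out$probs) <- c("s0_a", "s0_b", "s1_a", "s1_b")
  out
}

#' Save / load pre-determined walks
#'
#' Walks are stored as a plain CSV of four probability columns, one row per
#' trial, so a fixed ("pre-determined") walk set can be reused across
#' participants and sessions.
#'
#' @param walks a `reward_walks` object.
#' @param path file path.
#' @rdname walk_io
#' @export
write_walks_csv <- function(walks, path) {
  write.csv(as.data.frame(walks$probs), path, row.names = FALSE)
  invisible(path)
}

#' @param bounds reflecting bounds to record on the loaded object.
#' @rdname walk_io
#' @export
read_walks_csv <- function(path, bounds = c(0.25, 0.75)) {
  m <- as.matrix(read.csv(path))
  if (ncol(m) != 4) stopf("walk file must have exactly 4 columns, got %d", ncol(m))
  if (any(m < 0 | m > 1)) stopf("walk file contains values outside [0, 1]")
  colnames(m) <- c("s0_a", "s0_b", "s1_a", "s1_b")
  structure(list(probs = m, step_sd = NA_real_, bounds = bounds, seed = NA_integer_),
            class = "reward_walks")
}

#' Sample a second-stage state given a first-stage action
#'
#' @param c1 first-stage action, 0 or 1.
#' @param structure a [transition_structure()].
#' @return a list with `state` (0 or 1) and `transition`
#'   (`"common"` or `"rare"`). Uses the current RNG stream.
#' @export
sample_transition <- function(c1, structure = transition_structure()) {
  if (!c1 %in% c(0L, 1L)) stopf("c1 must be 0 or 1")
  is_common <- runif(1) < structure$common_prob
  state <- if (is_common) structure$common_state[c1 + 1L] else
    structure$common_state[2L - c1]
  list(state = as.integer(state),
       transition = if (is_common) "common" else "rare")
}

#' Run one session of the task under an arbitrary choice policy
#'
#' Steps the environment trial by trial, asking `policy` for each choice.
#' This is the generic engine used for scripted or degenerate agents; the
#' hybrid learner has its own fast generative path in [simulate_agent()].
#'
#' @param policy `function(t, stage, state, history)` returning 0, 1 or `NA`
#'   (omitted response). `stage` is 1 or 2; `state` is the visited state at
#'   stage 2 (`NA` at stage 1); `history` is the data.frame of completed
#'   trials so far.
#' @param walks a `reward_walks` object with at least `n_trials` rows.
#' @param config a [task_config()].
#' @param subject_id,group,session metadata stored on the result.
#' @return a `twostep_session` object (see [twostep_session()]).
#' @export
run_session <- function(policy, walks, config = task_config(),
                        subject_id = "sim", group = "unknown",
                        session = "baseline") {
  n <- config$n_trials
  if (nrow(walks$probs) < n) {
    stopf("walks provide %d trials but config requires %d", nrow(walks$probs), n)
  }
  tr <- empty_trials(n)
  for (t in seq_len(n)) {
    c1 <- policy(t, 1L, NA_integer_, tr[seq_len(t - 1L), , drop = FALSE])
    if (is.na(c1)) next                       # missing stage 1 voids the trial
    tr$c1[t] <- as.integer(c1)
    out <- sample_transition(c1, config$structure)
    tr$state[t] <- out$state
    tr$transition[t] <- out$transition
    c2 <- policy(t, 2L, out$state, tr[seq_len(t - 1L), , drop = FALSE])
    if (is.na(c2)) next
    tr$c2[t] <- as.integer(c2)
    tr$reward[t] <- rbinom(1, 1, walks$probs[t, 2L * out$state + c2 + 1L])
  }
  twostep_session(subject_id, group, session, tr,
                  walk_ref = config$counterbalance_id)
}

empty_trials <- function(n) {
  data.frame(
    t = seq_len(n), c1 = rep(NA_integer_, n), side1 = rep(NA_character_, n),
    transition = rep(NA_character_, n), state = rep(NA_integer_, n),
    c2 = rep(NA_integer_, n), side2 = rep(NA_character_, n),
    reward = rep(NA_integer_, n),
    rt1 = rep(NA_real_, n), rt2 = rep(NA_real_, n), stringsAsFactors = FALSE
  )
}

#' Construct a session record
#'
#' A `twostep_session` is one participant-session's trial log: metadata plus
#' a data.frame of trials with columns `t`, `c1`, `side1`, `transition`,
#' `state`, `c2`, `side2`, `reward`, `rt1`, `rt2`. Choices, states and
#' rewards are 0/1 integers with `NA` marking omitted responses; a missing
#' first-stage response voids all downstream fields of that trial.
#'
#' @param subject_id participant label.
#' @param group `"MUD"`, `"control"` or `"unknown"`.
#' @param session `"baseline"` or `"followup"`.
#' @param trials trial data.frame as above.
#' @param walk_ref counterbalance id of the walks used.
#' @return an object of class `twostep_session`.
#' @export
twostep_session <- function(subject_id, group, session, trials,
                            walk_ref = NA_integer_) {
  if (!session %in% c("baseline", "followup")) {
    stopf("session must be 'baseline' or 'followup'")
  }
  if (!identical(trials$t, seq_len(nrow(trials)))) {
    stopf("trial indices must run 1..n without gaps")
  }
  bad <- !is.na(trials$c1) & !is.na(trials$state) &
    ((trials$transition == "common") != (trials$state == trials$c1))
  if (any(bad, na.rm = TRUE)) {
    stopf("transition label inconsistent with (c1, state) at trial %d",
          trials$t[which(bad)[1]])
  }
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group), session = session,
                 trials = trials, walk_ref = walk_ref),
            class = "twostep_session")
}

#' @export
print.twostep_session <- function(x, ...) {
  n_valid <- sum(!is.na(x$trials$c1) & !is.na(x$trials$c2))
  cat(sprintf("<twostep_session> %s [%s, %s]: %d trials (%d complete)\n",
              x$subject_id, x$group, x$session, nrow(x$trials), n_valid))
  invisible(x)
}
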