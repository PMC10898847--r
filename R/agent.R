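#' Construct and validate a hybrid-agent parameter set
#'
#' The agent has five parameters: `alpha`, the shared learning and
#' forgetting/decay rate in `[0, 1]`; `beta_mb` and `beta_mf`, the
#' non-negative weights of the model-based and model-free first-stage
#' values; `beta_rep`, an unbounded bias toward (positive) or against
#' (negative) repeating the previous first-stage choice; and
#' `beta_consistency`, the non-negative second-stage inverse temperature.
#'
#' @param alpha,beta_mb,beta_mf,beta_rep,beta_consistency numeric scalars.
#' @return a named numeric vector of class `twostep_params`.
#' @export
parameter_set <- function(alpha, beta_mb, beta_mf, beta_rep, beta_consistency) {
  p <- c(alpha = unname(alpha), beta_mb = unname(beta_mb),
         beta_mf = unname(beta_mf), beta_rep = unname(beta_rep),
         beta_consistency = unname(beta_consistency))
  if (any(!is.finite(p))) stopf("parameters must be finite")
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (beta_mb < 0 || beta_mf < 0 || beta_consistency < 0) {
    stopf("beta_mb, beta_mf and beta_consistency must be non-negative")
  }
  structure(p, class = "twostep_params")
}

param_names <- c("alpha", "beta_mb", "beta_mf", "beta_rep", "beta_consistency")

as_param_vector <- function(params) {
  if (is.list(params)) params <- unlist(params)
  p <- unname(params[param_names])
  if (any(is.na(p))) stopf("params must supply %s", paste(param_names, collapse = ", "))
  p
}

#' Second-stage value update
#'
#' The chosen option's value decays by `1 - alpha` and absorbs the reward:
#' `q' = (1 - alpha) * q + r`.
#'
#' @param q current value. @param alpha learning rate. @param r reward (0/1).
#' @return updated value.
#' @export
update_stage2 <- function(q, alpha, r) (1 - alpha) * q + r

#' Model-based first-stage values
#'
#' Each first-stage action is valued prospectively as the maximum of the two
#' second-stage option values in that action's *common* destination state.
#'
#' @param q_stage2 2x2 matrix of second-stage values (rows = states,
#'   columns = options).
#' @param structure a [transition_structure()].
#' @return length-2 vector of model-based values for actions 0 and 1.
#' @export
mb_stage1_values <- function(q_stage2, structure = transition_structure()) {
  vapply(1:2, function(a) max(q_stage2[structure$common_state[a] + 1L, ]),
         numeric(1))
}

#' Latent value state
#'
#' @return a list with `q1` (length-2 model-free first-stage values) and
#'   `q_stage2` (2x2 second-stage values), all initialized to 0.
#' @export
latent_values <- function() {
  list(q1 = c(0, 0), q_stage2 = matrix(0, 2, 2))
}

#' One-trial model-free update (including forgetting)
#'
#' After a complete trial, the chosen second-stage option updates via
#' [update_stage2()]; the chosen first-stage action's model-free value is
#' replaced by that freshly updated option value; and every unchosen value
#' (the other first-stage action and the three unchosen options) decays by
#' `1 - alpha`. A trial with a missing response leaves the values unchanged.
#'
#' @param values a [latent_values()] list.
#' @param trial one-row trial data.frame (columns `c1`, `state`, `c2`,
#'   `reward`).
#' @param alpha learning/forgetting rate.
#' @return the updated values list.
#' @export
mf_stage1_update <- function(values, trial, alpha) {
  c1 <- trial$c1; s <- trial$state; c2 <- trial$c2; r <- trial$reward
  if (is.na(c1) || is.na(s) || is.na(c2) || is.na(r)) return(values)
  upd <- update_stage2(values$q_stage2[s + 1L, c2 + 1L], alpha, r)
  values$q_stage2 <- values$q_stage2 * (1 - alpha)
  values$q_stage2[s + 1L, c2 + 1L] <- upd
  values$q1[c1 + 1L] <- upd
  values$q1[2L - c1] <- values$q1[2L - c1] * (1 - alpha)
  values
}

#' First-stage choice probabilities
#'
#' Softmax over `beta_mb * Q_MB + beta_mf * Q_MF + beta_rep * I`, where `I`
#' indicates repetition of the previous first-stage choice (0 for both
#' actions on the first trial, when there is no previous choice).
#'
#' @param values a [latent_values()] list.
#' @param params a [parameter_set()].
#' @param prev_c1 previous first-stage choice (0, 1 or `NA`).
#' @param structure a [transition_structure()].
#' @return probabilities for actions 0 and 1 (sum to 1).
#' @export
stage1_choice_probs <- function(values, params, prev_c1 = NA,
                                structure = transition_structure()) {
  p <- as_param_vector(params)
  qmb <- mb_stage1_values(values$q_stage2, structure)
  rep_ind <- if (is.na(prev_c1)) c(0, 0) else as.numeric(0:1 == prev_c1)
  softmax(p[2] * qmb + p[3] * values$q1 + p[4] * rep_ind)
}

#' Second-stage choice probabilities
#'
#' Softmax over the visited state's two option values with inverse
#' temperature `beta_consistency`.
#'
#' @param q_stage2 2x2 second-stage value matrix.
#' @param s visited state (0 or 1).
#' @param params a [parameter_set()].
#' @return probabilities for options 0 and 1.
#' @export
stage2_choice_probs <- function(q_stage2, s, params) {
  p <- as_param_vector(params)
  softmax(p[5] * q_stage2[s + 1L, ])
}

session_arrays <- function(session) {
  tr <- session$trials
  na2neg <- function(x) { x <- as.integer(x); x[is.na(x)] <- -1L; x }
  list(c1 = na2neg(tr$c1), s = na2neg(tr$state), c2 = na2neg(tr$c2),
       r = na2neg(tr$reward))
}

#' Session log-likelihood of the hybrid agent
#'
#' Runs the latent-value recursion in trial order (all values start at 0;
#' per trial: first-stage softmax, transition, second-stage softmax, value
#' update, model-free assignment, forgetting decay) and sums the log
#' probabilities of the observed choices. Trials with a missing first-stage
#' response contribute nothing and do not update values; trials missing only
#' the second stage contribute the first-stage term.
#'
#' @param params a [parameter_set()] (or named vector/list).
#' @param session a `twostep_session`.
#' @param method `"fast"` (compiled recursion) or `"reference"` (plain R
#'   composition of the single-step operations, kept as an independent
#'   cross-check).
#' @return log-likelihood in nats (always <= 0).
#' @export
session_loglik <- function(params, session, method = c("fast", "reference")) {
  method <- match.arg(method)
  p <- as_param_vector(params)
  if (any(!is.finite(p))) stopf("parameters must be finite")
  a <- session_arrays(session)
  if (all(a$c1 < 0)) {
    warnf("session %s has no valid trials; log-likelihood is 0",
          session$subject_id)
    return(0)
  }
  if (method == "fast") {
    cpp_session_loglik(p, a$c1, a$s, a$c2, a$r)
  } else {
    reference_loglik(p, session)
  }
}

# naive per-trial stepping implementation built from the exported one-step
# operations; deliberately independent of the compiled path
reference_loglik <- function(p, session) {
  params <- parameter_set(p[1], p[2], p[3], p[4], p[5])
  values <- latent_values()
  prev <- NA_integer_
  ll <- 0
  for (i in seq_len(nrow(session$trials))) {
    trial <- session$trials[i, ]
    if (is.na(trial$c1)) next
    p1 <- stage1_choice_probs(values, params, prev)
    ll <- ll + log(p1[trial$c1 + 1L])
    prev <- trial$c1
    if (is.na(trial$state) || is.na(trial$c2) || is.na(trial$reward)) next
    p2 <- stage2_choice_probs(values$q_stage2, trial$state, params)
    ll <- ll + log(p2[trial$c2 + 1L])
    values <- mf_stage1_update(values, trial, p[1])
  }
  ll
}

#' Chance-model log-likelihood
#'
#' The screening null model assigns probability 0.5 to every observed choice
#' at both stages.
#'
#' @param session a `twostep_session`.
#' @return `(n valid stage-1 choices + n valid stage-2 choices) * log(0.5)`.
#' @export
chance_loglik <- function(session) {
  tr <- session$trials
  (sum(!is.na(tr$c1)) + sum(!is.na(tr$c2))) * log(0.5)
}

#' Simulate a session from the hybrid agent
#'
#' Generative counterpart of [session_loglik()]: first- and second-stage
#' choices are sampled from the model's softmax rules, transitions from the
#' 70/30 structure and rewards from the walk probabilities. Response sides
#' are assigned by randomizing the left/right placement of the two options
#' each trial; response times are drawn from a lognormal model.
#'
#' @param params a [parameter_set()].
#' @param walks a `reward_walks` object.
#' @param config a [task_config()].
#' @param subject_id,group,session metadata for the returned log.
#' @param missing_rate per-trial omission probability, applied independently
#'   to each stage.
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters (seconds).
#' @param side_bias probability that a response lands on the participant's
#'   preferred key *independently of the task* instead of following the
#'   choice; 0 for ordinary agents, near 1 reproduces single-key responding.
#' @return a `twostep_session`. Uses the current RNG stream; wrap in
#'   `set.seed()` for reproducibility.
#' @export
simulate_agent <- function(params, walks, config = task_config(),
                           subject_id = "sim", group = "unknown",
                           session = "baseline", missing_rate = 0,
                           rt_meanlog = log(0.7), rt_sdlog = 0.3,
                           side_bias = 0) {
  p <- as_param_vector(params)
  n <- config$n_trials
  if (nrow(walks$probs) < n) {
    stopf("walks provide %d trials but config requires %d",
          nrow(walks$probs), n)
  }
  miss1 <- runif(n) < missing_rate
  miss2 <- runif(n) < missing_rate
  sim <- cpp_simulate_session(p, walks$probs[seq_len(n), , drop = FALSE],
                              config$structure$common_prob, miss1, miss2)
  tr <- empty_trials(n)
  tr$c1 <- sim$c1; tr$state <- sim$s; tr$c2 <- sim$c2; tr$reward <- sim$r
  tr$transition <- ifelse(is.na(sim$common), NA_character_,
                          ifelse(sim$common, "common", "rare"))
  # left/right placement of option 0, randomized per trial and stage
  opt0_left1 <- runif(n) < 0.5
  opt0_left2 <- runif(n) < 0.5
  tr$side1 <- choice_side(tr$c1, opt0_left1)
  tr$side2 <- choice_side(tr$c2, opt0_left2)
  if (side_bias > 0) {
    # responses that follow a key preference rather than the choice
    forced1 <- !is.na(tr$c1) & runif(n) < side_bias
    forced2 <- !is.na(tr$c2) & runif(n) < side_bias
    tr$side1[forced1] <- "left"
    tr$side2[forced2] <- "left"
  }
  tr$rt1[!is.na(tr$c1)] <- rlnorm(sum(!is.na(tr$c1)), rt_meanlog, rt_sdlog)
  tr$rt2[!is.na(tr$c2)] <- rlnorm(sum(!is.na(tr$c2)), rt_meanlog, rt_sdlog)
  twostep_session(subject_id, group, session, tr,
                  walk_ref = config$counterbalance_id)
}

choice_side <- function(choice, opt0_left) {
  ifelse(is.na(choice), NA_character_,
         ifelse((choice == 0L) == opt0_left, "left", "right"))
}
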