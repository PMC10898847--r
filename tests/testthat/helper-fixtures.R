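# Shared fixtures: sessions are always built in code, never stored.

# hand-built session from explicit trial vectors; transition derived from
# (c1, state) so the invariant holds by construction
make_session <- function(c1, state, c2, reward, subject_id = "t1",
                         group = "unknown", session = "baseline",
                         rt1 = NULL, rt2 = NULL, side1 = NULL, side2 = NULL) {
  n <- length(c1)
  tr <- twosteprl:::empty_trials(n)
  tr$c1 <- as.integer(c1)
  tr$state <- as.integer(state)
  tr$c2 <- as.integer(c2)
  tr$reward <- as.integer(reward)
  tr$transition <- ifelse(is.na(tr$c1) | is.na(tr$state), NA_character_,
                          ifelse(tr$state == tr$c1, "common", "rare"))
  tr$rt1 <- if (is.null(rt1)) ifelse(is.na(tr$c1), NA_real_, 0.7) else rt1
  tr$rt2 <- if (is.null(rt2)) ifelse(is.na(tr$c2), NA_real_, 0.7) else rt2
  tr$side1 <- if (is.null(side1))
    ifelse(is.na(tr$c1), NA_character_, c("left", "right")[tr$c1 + 1L]) else side1
  tr$side2 <- if (is.null(side2))
    ifelse(is.na(tr$c2), NA_character_, c("left", "right")[tr$c2 + 1L]) else side2
  twostep_session(subject_id, group, session, tr)
}

# a complete random session with optional missingness, for oracle checks
random_session <- function(n = 20, missing_rate = 0, seed = 1,
                           subject_id = "r1", ...) {
  set.seed(seed)
  cfg <- task_config(n_trials = n)
  w <- generate_reward_walks(cfg, seed = seed + 100)
  p <- parameter_set(runif(1, 0.2, 0.8), exp(rnorm(1, 0, 0.5)),
                     exp(rnorm(1, 0, 0.5)), rnorm(1, 0.5, 0.5),
                     exp(rnorm(1, 0, 0.5)))
  list(session = simulate_agent(p, w, cfg, subject_id = subject_id,
                                missing_rate = missing_rate, ...),
       params = p, walks = w, config = cfg)
}

# constant-probability walks (for degenerate-reward tests)
constant_walks <- function(n, p = 1) {
  structure(list(probs = matrix(p, n, 4,
                                dimnames = list(NULL, c("s0_a", "s0_b",
                                                        "s1_a", "s1_b"))),
                 step_sd = 0, bounds = c(0, 1), seed = NA_integer_),
            class = "reward_walks")
}
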