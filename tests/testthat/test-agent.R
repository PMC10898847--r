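test_that("second-stage value update follows the decay-plus-reward rule", {
  expect_equal(update_stage2(0, 0.5, 1), 1.0)
  expect_equal(update_stage2(1, 0, 0), 1.0)
  expect_equal(update_stage2(0.8, 0.2, 1), 1.64)
})

test_that("model-based values take the max of the common state's options", {
  q <- matrix(0, 2, 2)
  expect_equal(mb_stage1_values(q), c(0, 0))
  q <- rbind(c(0.9, 0.1), c(0.3, 0.4))
  expect_equal(mb_stage1_values(q), c(0.9, 0.4))
  q_swapped <- rbind(c(0.1, 0.9), c(0.4, 0.3))
  expect_equal(mb_stage1_values(q_swapped), mb_stage1_values(q))
})

test_that("model-free update assigns the chosen option value and decays the rest", {
  trial <- data.frame(c1 = 0L, state = 1L, c2 = 0L, reward = 1L)

  v <- latent_values()
  out <- mf_stage1_update(v, trial, alpha = 0)
  expect_equal(out$q1, c(1, 0))

  v$q1 <- c(0.3, 0.8); v$q_stage2 <- matrix(0.5, 2, 2)
  out <- mf_stage1_update(v, trial, alpha = 1)
  expect_equal(out$q1, c(1, 0))          # chosen = r, unchosen fully decayed
  expect_equal(out$q_stage2[2, 1], 1)
  expect_equal(out$q_stage2[1, ], c(0, 0))

  v <- latent_values()
  v$q1 <- c(0, 0.8)
  v$q_stage2[2, 1] <- 0.5
  out <- mf_stage1_update(v, data.frame(c1 = 0L, state = 1L, c2 = 0L,
                                        reward = 0L), alpha = 0.3)
  expect_equal(out$q1[1], 0.35)          # (1-0.3)*0.5 + 0
  expect_equal(out$q1[2], 0.56)          # 0.8 * 0.7

  miss <- data.frame(c1 = NA_integer_, state = NA_integer_,
                     c2 = NA_integer_, reward = NA_integer_)
  expect_identical(mf_stage1_update(v, miss, 0.3), v)
})

test_that("choice probabilities are proper softmaxes with the stated limits", {
  v <- latent_values()
  p0 <- parameter_set(0.5, 0, 0, 0, 0)
  expect_equal(stage1_choice_probs(v, p0, NA), c(0.5, 0.5))
  expect_equal(stage2_choice_probs(v$q_stage2, 0, p0), c(0.5, 0.5))

  p_rep <- parameter_set(0.5, 0, 0, 40, 0)
  expect_gt(stage1_choice_probs(v, p_rep, prev_c1 = 0)[1], 1 - 1e-10)

  v$q_stage2 <- rbind(c(1, 0), c(0, 0))
  p_mb <- parameter_set(0.5, 2, 0, 0, 0)
  expect_equal(stage1_choice_probs(v, p_mb, NA)[1], exp(2) / (exp(2) + 1),
               tolerance = 1e-12)

  p_c <- parameter_set(0.5, 0, 0, 0, 1)
  expect_equal(stage2_choice_probs(rbind(c(1, 0), c(0, 0)), 0, p_c),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # equal values are split evenly at any temperature
  expect_equal(stage2_choice_probs(matrix(0.4, 2, 2), 1,
                                   parameter_set(0.5, 0, 0, 0, 7)),
               c(0.5, 0.5))

  # properness over random values and parameters
  set.seed(8)
  for (i in 1:25) {
    v$q1 <- rnorm(2); v$q_stage2 <- matrix(rnorm(4), 2)
    pp <- parameter_set(runif(1), exp(rnorm(1)), exp(rnorm(1)), rnorm(1),
                        exp(rnorm(1)))
    p1 <- stage1_choice_probs(v, pp, sample(c(NA, 0, 1), 1))
    p2 <- stage2_choice_probs(v$q_stage2, sample(0:1, 1), pp)
    expect_equal(sum(p1), 1); expect_true(all(p1 > 0))
    expect_equal(sum(p2), 1); expect_true(all(p2 > 0))
  }
})

test_that("repetition bias monotonically increases the stay probability", {
  v <- latent_values()
  v$q1 <- c(0.2, 0.6); v$q_stage2 <- matrix(runif(4), 2)
  p_stay <- vapply(seq(-2, 4, by = 0.5), function(b)
    stage1_choice_probs(v, parameter_set(0.4, 1, 1, b, 1), prev_c1 = 0)[1],
    numeric(1))
  expect_true(all(diff(p_stay) > 0))
})

test_that("session log-likelihood matches closed forms and stays non-positive", {
  sim <- random_session(n = 200, seed = 21)
  p0 <- parameter_set(0.5, 0, 0, 0, 0)
  expect_equal(session_loglik(p0, sim$session), 400 * log(0.5),
               tolerance = 1e-12)
  expect_equal(session_loglik(p0, sim$session), -277.259, tolerance = 1e-3)
  expect_lte(session_loglik(sim$params, sim$session), 0)

  miss <- random_session(n = 50, missing_rate = 0.3, seed = 22)
  n1 <- sum(!is.na(miss$session$trials$c1))
  n2 <- sum(!is.na(miss$session$trials$c2))
  expect_equal(session_loglik(p0, miss$session), (n1 + n2) * log(0.5),
               tolerance = 1e-12)

  expect_error(session_loglik(c(alpha = 0.5, beta_mb = Inf, beta_mf = 0,
                                beta_rep = 0, beta_consistency = 0),
                              sim$session), "finite")
  empty <- make_session(NA, NA, NA, NA)
  expect_warning(ll <- session_loglik(p0, empty), "no valid trials")
  expect_identical(ll, 0)
})

test_that("compiled likelihood equals the per-trial reference to 1e-10", {
  for (seed in 1:5) {
    sim <- random_session(n = 20, missing_rate = 0.15, seed = seed)
    set.seed(seed + 50)
    pp <- parameter_set(runif(1), exp(rnorm(1)), exp(rnorm(1)), rnorm(1),
                        exp(rnorm(1)))
    expect_equal(session_loglik(pp, sim$session, method = "fast"),
                 session_loglik(pp, sim$session, method = "reference"),
                 tolerance = 1e-10)
  }
})

test_that("chance model counts valid choices at both stages", {
  full <- random_session(n = 200, seed = 30)$session
  expect_equal(chance_loglik(full), 400 * log(0.5))
  gap <- random_session(n = 200, missing_rate = 0.05, seed = 31)$session
  n1 <- sum(!is.na(gap$trials$c1)); n2 <- sum(!is.na(gap$trials$c2))
  expect_equal(chance_loglik(gap), (n1 + n2) * log(0.5))
  expect_identical(chance_loglik(make_session(NA, NA, NA, NA)), 0)
})

test_that("simulated agents show the dominance and uniform limits", {
  cfg <- task_config(n_trials = 150)
  w <- generate_reward_walks(cfg, seed = 9)

  set.seed(41)
  rep_agent <- simulate_agent(parameter_set(0.5, 0, 0, 40, 0), w, cfg)
  c1 <- rep_agent$trials$c1
  expect_true(all(c1[-1] == c1[1]))

  set.seed(42)
  stays <- replicate(10, {
    s <- simulate_agent(parameter_set(0.5, 0, 0, 0, 0), w, cfg)
    mean(diff(s$trials$c1) == 0)
  })
  expect_lt(abs(mean(stays) - 0.5), 0.05)
})

test_that("a model-free agent stays after reward regardless of transition", {
  cfg <- task_config(n_trials = 200)
  w <- generate_reward_walks(cfg, seed = 10)
  set.seed(43)
  recs <- code_stay_records(lapply(1:10, function(i)
    simulate_agent(parameter_set(0.5, 0, 4, 0, 3), w, cfg,
                   subject_id = sprintf("mf%d", i))))
  stay_by <- tapply(recs$stay, list(recs$prev_win, recs$prev_transition), mean)
  # reward raises staying within both transition types
  expect_gt(stay_by["1", "1"], stay_by["-1", "1"])
  expect_gt(stay_by["1", "-1"], stay_by["-1", "-1"])
})

test_that("generating parameters out-predict strongly perturbed ones", {
  wins <- 0L
  for (seed in 1:6) {
    sim <- random_session(n = 200, seed = 100 + seed)
    truth <- as_vec <- unclass(sim$params)
    pert <- parameter_set(min(max(truth[1] + 0.4 * sign(0.5 - truth[1]), 0), 1),
                          truth[2] * 4, truth[3] * 0.1,
                          truth[4] - 1.5, truth[5] * 0.2)
    wins <- wins + (session_loglik(sim$params, sim$session) >
                      session_loglik(pert, sim$session))
  }
  expect_gte(wins, 5L)
})
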