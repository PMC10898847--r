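test_that("stay records code consecutive valid pairs as documented", {
  always_a <- make_session(rep(0L, 6), rep(0L, 6), rep(0L, 6), rep(1L, 6))
  expect_true(all(code_stay_records(list(always_a))$stay == 1))

  alt <- make_session(rep(0:1, 3), rep(0:1, 3), rep(0L, 6), rep(1L, 6))
  expect_true(all(code_stay_records(list(alt))$stay == 0))

  # choices A,A,B,B; rewards 1,0,1,0; transitions c,c,r,c
  toy <- make_session(c1 = c(0, 0, 1, 1), state = c(0, 0, 0, 1),
                      c2 = c(0, 1, 0, 1), reward = c(1, 0, 1, 0))
  rec <- code_stay_records(list(toy))
  expect_identical(rec$stay, c(1L, 0L, 1L))
  expect_identical(rec$prev_win, c(1, -1, 1))
  expect_identical(rec$prev_transition, c(1, 1, -1))

  # a missing middle trial removes both adjacent pairs
  gap <- make_session(c1 = c(0, NA, 0, 0), state = c(0, NA, 0, 0),
                      c2 = c(0, NA, 0, 0), reward = c(1, NA, 1, 1))
  expect_identical(nrow(code_stay_records(list(gap))), 1L)
})

test_that("flipping the previous-win coding flips its coefficient exactly", {
  set.seed(61)
  cfg <- task_config(n_trials = 150)
  w <- generate_reward_walks(cfg, seed = 61)
  sessions <- lapply(1:10, function(i)
    simulate_agent(parameter_set(0.5, 0.5, 2, 0.5, 2.5), w, cfg,
                   subject_id = sprintf("s%02d", i),
                   group = if (i <= 5) "MUD" else "control"))
  rec <- code_stay_records(sessions)
  f1 <- fit_stay_glmm(rec, random_slopes = FALSE)
  rec2 <- rec; rec2$prev_win <- -rec2$prev_win
  f2 <- fit_stay_glmm(rec2, random_slopes = FALSE)
  b1 <- f1$terms$estimate[f1$terms$term == "prev_win"]
  b2 <- f2$terms$estimate[f2$terms$term == "prev_win"]
  expect_equal(b1, -b2, tolerance = 1e-4)
})

test_that("a degenerate all-stay outcome raises a separation error", {
  rec <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 4),
                    group = rep(c("MUD", "control"), each = 8),
                    time = "baseline", stay = 1L,
                    prev_win = rep(c(-1, 1), 8),
                    prev_transition = rep(c(-1, -1, 1, 1), 4))
  expect_error(fit_stay_glmm(rec), "separation")
})

test_that("the GLMM matches plain logistic regression without heterogeneity", {
  set.seed(62)
  n <- 4000
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = n / 10),
                  group = "control", time = "baseline",
                  prev_win = sample(c(-1, 1), n, TRUE),
                  prev_transition = sample(c(-1, 1), n, TRUE))
  eta <- 0.8 + 0.5 * d$prev_win + 0.2 * d$prev_win * d$prev_transition
  d$stay <- rbinom(n, 1, plogis(eta))
  fg <- suppressMessages(fit_stay_glmm(d, random_slopes = FALSE))
  glm_fit <- glm(stay ~ prev_win * prev_transition, data = d,
                 family = binomial())
  shared <- c("(Intercept)", "prev_win", "prev_transition",
              "prev_win:prev_transition")
  expect_equal(fg$terms$estimate[match(shared, fg$terms$term)],
               unname(coef(glm_fit)[shared]), tolerance = 0.05)
})

test_that("reward-insensitive groups show the negative Group x Win sign", {
  set.seed(63)
  cfg <- task_config(n_trials = 200)
  w <- generate_reward_walks(cfg, seed = 63)
  sessions <- c(
    lapply(1:10, function(i) simulate_agent(
      parameter_set(0.5, 0, 3, 0.3, 3), w, cfg,
      subject_id = sprintf("c%02d", i), group = "control")),
    lapply(1:10, function(i) simulate_agent(
      parameter_set(0.5, 0, 0, 0.3, 3), w, cfg,
      subject_id = sprintf("m%02d", i), group = "MUD")))
  fit <- fit_stay_glmm(code_stay_records(sessions))
  gw <- fit$terms[fit$terms$term == "prev_win:group", ]
  expect_lt(gw$or, 1)
  expect_lt(gw$p, 0.05)

  mm <- marginal_means_posthoc(fit)
  expect_true(all(c("emmeans", "contrasts") %in% names(mm)))
  expect_true(all(mm$contrasts$p_adj >= 0 & mm$contrasts$p_adj <= 1))
})

test_that("null models yield near-unit group contrasts with large adjusted p", {
  set.seed(64)
  cfg <- task_config(n_trials = 150)
  w <- generate_reward_walks(cfg, seed = 64)
  sessions <- lapply(1:16, function(i) simulate_agent(
    parameter_set(0.5, 0.5, 1.5, 0.5, 2), w, cfg,
    subject_id = sprintf("s%02d", i),
    group = if (i %% 2) "MUD" else "control"))
  fit <- fit_stay_glmm(code_stay_records(sessions))
  mm <- marginal_means_posthoc(fit)
  between <- grepl("group0.*group1|group1.*group0", mm$contrasts$contrast)
  same_win <- mapply(function(ctr) {
    length(unique(regmatches(ctr, gregexpr("prev_win-?1", ctr))[[1]])) == 1
  }, mm$contrasts$contrast)
  pure_group <- between & same_win
  expect_true(all(mm$contrasts$p_adj[pure_group] > 0.05))
  expect_true(all(abs(log(mm$contrasts$or[pure_group])) < 1))
})

test_that("rank-sum comparisons match exact enumeration and rank properties", {
  tab <- data.frame(group = rep(c("MUD", "control"), each = 3),
                    beta_mf = c(1, 2, 3, 10, 11, 12))
  res <- compare_parameter_groups(tab, "beta_mf")
  expect_identical(unname(res$statistic), 0)
  expect_equal(res$p, 0.1)
  expect_match(res$direction, "MUD < control")

  tab$beta_mf <- exp(tab$beta_mf)            # monotone transform invariance
  res2 <- compare_parameter_groups(tab, "beta_mf")
  expect_identical(res2$statistic, res$statistic)
  expect_equal(res2$p, res$p)

  tab$beta_mf <- 1
  expect_warning(res3 <- compare_parameter_groups(tab, "beta_mf"), "constant")
  expect_equal(res3$p, 1)

  expect_error(compare_parameter_groups(
    data.frame(group = c("MUD", "MUD", "control"), beta_mf = 1:3), "beta_mf"),
    "at least 3")
})

test_that("group-by-time ANOVA detects time shifts and respects symmetry", {
  set.seed(65)
  base <- rnorm(20)
  pt <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:20), each = 2),
    group = rep(rep(c("MUD", "control"), each = 10), each = 2)[1:40],
    session = rep(c("baseline", "followup"), 20),
    alpha = rep(base, each = 2) + rep(c(0, 1.5), 20) + rnorm(40, 0, 0.2))
  res <- anova_group_by_time(pt, "alpha")
  expect_lt(res$p[res$effect == "time"], 1e-6)
  expect_gt(res$p[res$effect == "group:time"], 0.05)

  flipped <- pt
  flipped$group <- ifelse(pt$group == "MUD", "control", "MUD")
  res_f <- anova_group_by_time(flipped, "alpha")
  expect_equal(res_f$F, res$F, tolerance = 1e-9)

  # subjects lacking a session are dropped with a message
  expect_message(anova_group_by_time(pt[-1, ], "alpha"), "dropping")
})

test_that("use-pattern correlations find planted monotone links", {
  set.seed(66)
  n <- 26
  pt <- data.frame(subject_id = sprintf("m%02d", 1:n), group = "MUD",
                   alpha = runif(n), beta_mb = exp(rnorm(n)),
                   beta_mf = exp(rnorm(n)), beta_rep = rnorm(n),
                   beta_consistency = exp(rnorm(n)))
  use <- data.frame(subject_id = pt$subject_id,
                    days_since_last_use = round(runif(n, 1, 60)),
                    frequency_of_use = scale(log(pt$beta_consistency)) +
                      rnorm(n, 0, 0.4))
  res <- correlate_params_use(pt, use)
  expect_gt(res$spearman["beta_consistency", "frequency_of_use"], 0.5)
  reg <- res$regressions$frequency_of_use
  expect_lt(reg$p, 0.05)
  expect_true(all(reg$vif < 10))

  # orthogonal predictors carry VIFs near 1
  expect_true(all(abs(res$regressions$frequency_of_use$vif - 1) < 1.5))

  # outlier rules drop extreme rows before fitting
  use2 <- use; use2$days_since_last_use[1] <- 151
  res2 <- correlate_params_use(pt, use2,
                               outlier_rules = list(days_since_last_use = c(0, 150)))
  expect_identical(res2$regressions$frequency_of_use$n, as.integer(n - 1))

  expect_error(correlate_params_use(pt[1:6, ], use[1:6, ]), "complete cases")
})
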