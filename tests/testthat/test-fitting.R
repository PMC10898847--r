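test_that("parameter transforms are inverse bijections with stated anchors", {
  expect_equal(to_unconstrained(parameter_set(0.5, 1, 1, 0, 1)),
               c(0, 0, 0, 0, 0))
  set.seed(6)
  max_err <- 0
  for (i in 1:1000) {
    p <- parameter_set(runif(1, 1e-4, 1 - 1e-4), exp(rnorm(1, 0, 2)),
                       exp(rnorm(1, 0, 2)), rnorm(1, 0, 3), exp(rnorm(1, 0, 2)))
    back <- to_natural(to_unconstrained(p))
    max_err <- max(max_err, max(abs(unclass(back) - unclass(p))))
  }
  expect_lt(max_err, 1e-9)
  expect_warning(th <- to_unconstrained(parameter_set(0, 1, 1, 0, 1)),
                 "clipped")
  expect_true(all(is.finite(th)))
})

test_that("a near-degenerate prior dominates the MAP estimate", {
  sim <- random_session(n = 60, seed = 55)
  theta0 <- c(0.5, -0.2, 0.3, 0.8, 0.1)
  prior <- prior_model(theta0, diag(1e-6, 5))
  set.seed(1)
  fit <- map_fit_subject(list(sim$session), prior, n_starts = 2, n_fits = 3)
  expect_equal(unclass(fit$params[[1]]), unclass(to_natural(theta0)),
               tolerance = 1e-2)
})

test_that("the penalized objective decomposes into data and prior terms", {
  sim <- random_session(n = 40, seed = 56)
  prior <- twosteprl:::default_prior(5)
  set.seed(2)
  fit <- map_fit_subject(list(sim$session), prior, n_starts = 3, n_fits = 5)
  lp <- twosteprl:::log_prior_density(fit$theta, prior)
  expect_equal(fit$map_loglik, sum(fit$data_loglik) + lp, tolerance = 1e-6)
  expect_lte(sum(fit$data_loglik), 0)
})

test_that("more restarts never worsen the best objective", {
  sim <- random_session(n = 40, seed = 57)
  prior <- twosteprl:::default_prior(5)
  set.seed(11)
  f_few <- map_fit_subject(list(sim$session), prior, n_starts = 4, n_fits = 4)
  set.seed(11)
  f_many <- map_fit_subject(list(sim$session), prior, n_starts = 4, n_fits = 8)
  expect_gte(f_many$map_loglik, f_few$map_loglik - 1e-9)
})

test_that("MAP recovers generating parameters from informative data", {
  cfg <- task_config(n_trials = 200)
  w <- generate_reward_walks(cfg, seed = 14)
  truth <- parameter_set(0.5, 1, 2, 0.7, 2.5)
  set.seed(3)
  s <- simulate_agent(truth, w, cfg)
  fit <- map_fit_subject(list(s), prior_model(rep(0, 5), diag(9, 5)),
                         n_starts = 5, n_fits = 10)
  est <- unclass(fit$params[[1]])
  expect_lt(abs(est["alpha"] - 0.5), 0.2)
  expect_lt(abs(log(est["beta_mf"]) - log(2)), 0.8)
  expect_lt(abs(log(est["beta_consistency"]) - log(2.5)), 0.8)
})

test_that("EM shrinks toward the shared optimum for identical subjects", {
  sim <- random_session(n = 80, seed = 58)
  subjects <- list(a = list(sim$session), b = list(sim$session),
                   c = list(sim$session))
  subjects$b[[1]]$subject_id <- "b"; subjects$c[[1]]$subject_id <- "c"
  set.seed(4)
  em <- em_fit_population(subjects, n_starts = 4, n_fits = 8, max_iter = 15)
  thetas <- do.call(rbind, lapply(em$fits, `[[`, "theta"))
  expect_lt(max(abs(sweep(thetas, 2, em$prior$mu))), 0.35)
})

test_that("EM recovers the population mean of a simulated cohort", {
  mu_star <- c(0.2, -0.4, 0.5, 0.6, 0.4)
  sd_star <- rep(0.4, 5)
  cfg <- task_config(n_trials = 150)
  w <- generate_reward_walks(cfg, seed = 15)
  set.seed(16)
  subjects <- lapply(1:16, function(i) {
    th <- mu_star + sd_star * rnorm(5)
    list(simulate_agent(to_natural(th), w, cfg,
                        subject_id = sprintf("p%02d", i)))
  })
  names(subjects) <- sprintf("p%02d", 1:16)
  em <- em_fit_population(subjects, n_starts = 5, n_fits = 10, max_iter = 20)
  expect_true(em$n_iter >= 2)
  expect_lt(max(abs(em$prior$mu - mu_star)), 0.5)
})

test_that("mixed one/two-session cohorts fit with marginal priors", {
  cfg <- task_config(n_trials = 80)
  w <- generate_reward_walks(cfg, seed = 17)
  set.seed(18)
  mk <- function(id, both) {
    ss <- list(simulate_agent(parameter_set(0.5, 1, 1.5, 0.5, 2), w, cfg,
                              subject_id = id, session = "baseline"))
    if (both) ss <- c(ss, list(simulate_agent(
      parameter_set(0.5, 1, 1.5, 0.5, 2), w, cfg, subject_id = id,
      session = "followup")))
    ss
  }
  subjects <- list(a = mk("a", TRUE), b = mk("b", TRUE), c = mk("c", FALSE),
                   d = mk("d", TRUE))
  em <- em_fit_population(subjects, n_starts = 3, n_fits = 5, max_iter = 5)
  expect_identical(em$prior$dim, 10L)
  expect_length(em$fits$c$theta, 5L)
  expect_length(em$fits$a$theta, 10L)
  expect_length(em$fits$a$params, 2L)

  # a cohort with only baseline sessions drops to dimension 5
  base_only <- lapply(subjects[c("a", "b", "d")], function(ss) ss[1])
  em5 <- em_fit_population(base_only, n_starts = 3, n_fits = 5, max_iter = 5)
  expect_identical(em5$prior$dim, 5L)
})

test_that("chance screen excludes random responders and keeps learners", {
  cfg <- task_config(n_trials = 200)
  w <- generate_reward_walks(cfg, seed = 19)
  prior <- twosteprl:::default_prior(5)
  set.seed(20)

  rand_s <- simulate_agent(parameter_set(0.5, 0, 0, 0, 0), w, cfg)
  fit_r <- map_fit_subject(list(rand_s), prior, n_starts = 4, n_fits = 8)
  lrt_r <- lrt_vs_chance(fit_r, list(rand_s))
  expect_lt(abs(lrt_r$statistic), 12)
  expect_true(lrt_r$excluded)

  mf_s <- simulate_agent(parameter_set(0.5, 0, 5, 0, 3), w, cfg)
  fit_m <- map_fit_subject(list(mf_s), prior, n_starts = 4, n_fits = 8)
  lrt_m <- lrt_vs_chance(fit_m, list(mf_s))
  expect_lt(lrt_m$p, 0.05)
  expect_false(lrt_m$excluded)
  expect_identical(lrt_m$df, 5L)
})

test_that("fit_cohort tabulates parameters with LRT flags", {
  cfg <- task_config(n_trials = 100)
  w <- generate_reward_walks(cfg, seed = 23)
  set.seed(24)
  sessions <- c(
    lapply(1:3, function(i) simulate_agent(parameter_set(0.5, 1, 2, 0.5, 2.5),
                                           w, cfg, subject_id = sprintf("g%d", i),
                                           group = "control")),
    list(simulate_agent(parameter_set(0.5, 0, 0, 0, 0), w, cfg,
                        subject_id = "noise", group = "MUD")))
  cf <- fit_cohort(sessions, n_starts = 3, n_fits = 6, max_iter = 6)
  expect_identical(nrow(cf$table), 4L)
  expect_true(all(c("alpha", "beta_mf", "lrt_p", "excluded") %in%
                    names(cf$table)))
  expect_true(cf$table$excluded[cf$table$subject_id == "noise"])
  expect_true(all(cf$table$data_loglik <= 0))
})
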