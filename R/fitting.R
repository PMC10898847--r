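#' Gaussian population prior on unconstrained parameters
#'
#' @param mu mean vector (length 5 for single-session cohorts, 10 for
#'   two-session cohorts: baseline block first, follow-up block second).
#' @param sigma covariance matrix, symmetric positive-definite.
#' @return an object of class `prior_model`.
#' @export
prior_model <- function(mu, sigma) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  d <- length(mu)
  if (!all(dim(sigma) == d)) stopf("sigma must be %d x %d", d, d)
  if (max(abs(sigma - t(sigma))) > 1e-8) stopf("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("sigma must be positive-definite")
  structure(list(mu = mu, sigma = sigma, dim = d), class = "prior_model")
}

default_prior <- function(dim) {
  prior_model(rep(0, dim), diag(4, dim))
}

prior_marginal <- function(prior, idx) {
  prior_model(prior$mu[idx], prior$sigma[idx, idx, drop = FALSE])
}

log_prior_density <- function(theta, prior) {
  u <- chol(prior$sigma)
  z <- backsolve(u, theta - prior$mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(u))) - prior$dim / 2 * log(2 * pi)
}

theta_to_nat_vec <- function(th) {
  c(1 / (1 + exp(-th[1])), exp(th[2]), exp(th[3]), th[4], exp(th[5]))
}

# penalized negative objective for one subject: -(sum of session
# log-likelihoods + log prior density), theta stacked 5 per session
make_neg_objective <- function(arrs, prior) {
  u <- chol(prior$sigma)
  logdet_term <- sum(log(diag(u))) + prior$dim / 2 * log(2 * pi)
  mu <- prior$mu
  function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
    ll <- 0
    for (k in seq_along(arrs)) {
      blk <- theta[(5 * (k - 1) + 1):(5 * k)]
      a <- arrs[[k]]
      ll <- ll + cpp_session_loglik(theta_to_nat_vec(blk), a$c1, a$s, a$c2, a$r)
    }
    z <- backsolve(u, theta - mu, transpose = TRUE)
    -(ll - 0.5 * sum(z^2) - logdet_term)
  }
}

# central finite-difference gradient; more accurate than the optimizer's
# built-in forward differences, which matters near the optimum
central_grad <- function(f, h = 1e-5) {
  function(theta) {
    g <- numeric(length(theta))
    for (j in seq_along(theta)) {
      e <- numeric(length(theta)); e[j] <- h
      g[j] <- (f(theta + e) - f(theta - e)) / (2 * h)
    }
    g
  }
}

order_sessions <- function(sessions) {
  sessions[order(match(vapply(sessions, `[[`, "", "session"),
                       c("baseline", "followup")))]
}

#' Fit one subject by maximum a posteriori with multi-start optimization
#'
#' Maximizes the sum of the subject's session log-likelihoods plus the log
#' Gaussian prior density over the stacked unconstrained parameter vector
#' (5 entries per session). `n_fits` quasi-Newton runs are launched from
#' `n_starts` distinct starting points drawn from the prior (re-used with
#' jitter when `n_fits > n_starts`); the best objective wins.
#'
#' @param sessions a list of 1–2 `twostep_session` for one subject
#'   (baseline first).
#' @param prior a [prior_model()] of matching dimension.
#' @param n_starts number of distinct start points.
#' @param n_fits total optimizer runs.
#' @param incumbent optional theta used as the first start (warm restart).
#' @return a list of class `map_fit`: `theta`, per-session [parameter_set()]
#'   in `params`, `map_loglik` (penalized objective at the optimum),
#'   `data_loglik` per session, `posterior_cov` (Laplace), `converged`,
#'   `n_restarts_used`. Uses the current RNG stream.
#' @export
map_fit_subject <- function(sessions, prior, n_starts = 10L, n_fits = 50L,
                            incumbent = NULL) {
  sessions <- order_sessions(sessions)
  d <- 5L * length(sessions)
  if (prior$dim != d) stopf("prior dimension %d does not match %d session(s)",
                            prior$dim, length(sessions))
  arrs <- lapply(sessions, session_arrays)
  negf <- make_neg_objective(arrs, prior)

  u <- chol(prior$sigma)
  draw_start <- function() as.numeric(prior$mu + t(u) %*% rnorm(d))
  starts <- lapply(seq_len(max(1L, n_starts)), function(i) draw_start())
  if (!is.null(incumbent)) starts <- c(list(incumbent), starts)

  best <- NULL
  for (i in seq_len(max(1L, n_fits))) {
    s0 <- starts[[((i - 1L) %% length(starts)) + 1L]]
    if (i > length(starts)) s0 <- s0 + rnorm(d, 0, 0.25)
    fit <- tryCatch(
      optim(s0, negf, gr = central_grad(negf), method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("all optimizer restarts failed")

  theta <- best$par
  h <- tryCatch(optimHess(theta, negf), error = function(e) NULL)
  post_cov <- laplace_cov(h, d)
  data_ll <- vapply(seq_along(arrs), function(k) {
    blk <- theta[(5 * (k - 1) + 1):(5 * k)]
    a <- arrs[[k]]
    cpp_session_loglik(theta_to_nat_vec(blk), a$c1, a$s, a$c2, a$r)
  }, numeric(1))
  names(data_ll) <- vapply(sessions, `[[`, "", "session")

  structure(list(
    subject_id = sessions[[1]]$subject_id,
    session_labels = names(data_ll),
    theta = theta,
    params = lapply(seq_along(arrs), function(k)
      to_natural(theta[(5 * (k - 1) + 1):(5 * k)])),
    map_loglik = -best$value,
    data_loglik = data_ll,
    posterior_cov = post_cov,
    converged = best$convergence == 0,
    n_restarts_used = max(1L, n_fits)
  ), class = "map_fit")
}

# posterior covariance from the Hessian of the negative log posterior,
# eigenvalue-floored so a flat direction cannot produce a singular matrix
laplace_cov <- function(h, d) {
  if (is.null(h) || any(!is.finite(h))) return(diag(1, d))
  h <- (h + t(h)) / 2
  e <- eigen(h, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  v <- e$vectors
  v %*% diag(1 / vals, d) %*% t(v)
}

#' Hierarchical empirical-Bayes fit of a cohort
#'
#' Expectation-maximization over a Gaussian population prior on the
#' unconstrained parameters. The E-step computes each subject's MAP estimate
#' and Laplace posterior covariance under the current prior; the M-step
#' re-estimates the prior mean and covariance from those posteriors. When a
#' cohort mixes one- and two-session subjects, single-session subjects are
#' fit under the corresponding 5-dimensional marginal prior and contribute
#' to the M-step through the conditional Gaussian expectation of their
#' missing block. Iteration stops when the prior mean moves less than `tol`
#' (max absolute change) or after `max_iter` iterations.
#'
#' @param subject_sessions named list; each element is the list of 1–2
#'   sessions belonging to one subject.
#' @param init optional initial [prior_model()]; defaults to a broad
#'   zero-mean prior.
#' @param max_iter,tol EM stopping rule.
#' @param n_starts,n_fits multi-start budget for the first E-step; later
#'   E-steps warm-start from the incumbent with `n_fits_warm` runs.
#' @param n_fits_warm optimizer runs per subject after the first iteration.
#' @param diagonal if `TRUE`, the prior covariance is constrained diagonal.
#' @param verbose print per-iteration progress.
#' @return a list of class `em_fit`: `prior` (final [prior_model()]), `fits`
#'   (per-subject `map_fit`), `n_iter`, `converged`, and `trace` (approximate
#'   marginal likelihood per iteration).
#' @export
em_fit_population <- function(subject_sessions, init = NULL, max_iter = 30L,
                              tol = 1e-2, n_starts = 10L, n_fits = 50L,
                              n_fits_warm = 4L, diagonal = FALSE,
                              verbose = FALSE) {
  if (length(subject_sessions) < 2) stopf("need at least 2 subjects")
  subject_sessions <- lapply(subject_sessions, order_sessions)
  labels_all <- unique(unlist(lapply(subject_sessions, function(ss)
    vapply(ss, `[[`, "", "session"))))
  two_session <- "followup" %in% labels_all && "baseline" %in% labels_all
  d <- if (two_session) 10L else 5L
  block_of <- function(lab) if (lab == "followup" && two_session) 6:10 else 1:5
  idx_of <- function(ss) unlist(lapply(ss, function(s) block_of(s$session)))

  prior <- init %||% default_prior(d)
  if (prior$dim != d) stopf("init prior has dimension %d, cohort needs %d",
                            prior$dim, d)
  incumbents <- vector("list", length(subject_sessions))
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    fits <- vector("list", length(subject_sessions))
    marg <- 0
    for (i in seq_along(subject_sessions)) {
      ss <- subject_sessions[[i]]
      idx <- idx_of(ss)
      pr_i <- if (length(idx) == d) prior else prior_marginal(prior, idx)
      if (iter == 1L) {
        fits[[i]] <- map_fit_subject(ss, pr_i, n_starts, n_fits)
      } else {
        fits[[i]] <- map_fit_subject(ss, pr_i, n_starts = 2L,
                                     n_fits = n_fits_warm,
                                     incumbent = incumbents[[i]])
      }
      incumbents[[i]] <- fits[[i]]$theta
      di <- length(idx)
      marg <- marg + fits[[i]]$map_loglik + di / 2 * log(2 * pi) +
        0.5 * determinant(fits[[i]]$posterior_cov)$modulus
    }
    trace <- c(trace, as.numeric(marg))

    mom <- m_step_moments(fits, subject_sessions, prior, d, idx_of)
    mu_new <- mom$mu
    sigma_new <- mom$sigma
    if (diagonal) sigma_new <- diag(diag(sigma_new), d)
    sigma_new <- ensure_pd(sigma_new)
    delta <- max(abs(mu_new - prior$mu))
    prior <- prior_model(mu_new, sigma_new)
    if (verbose) {
      message(sprintf("EM iter %d: marg %.2f, mean shift %.4f", iter, marg, delta))
    }
    if (delta < tol) { converged <- TRUE; break }
  }

  names(fits) <- names(subject_sessions)
  structure(list(prior = prior, fits = fits, n_iter = iter,
                 converged = converged, trace = trace),
            class = "em_fit")
}

m_step_moments <- function(fits, subject_sessions, prior, d, idx_of) {
  n <- length(fits)
  sum_t <- numeric(d)
  sum_tt <- matrix(0, d, d)
  for (i in seq_len(n)) {
    idx <- idx_of(subject_sessions[[i]])
    theta_o <- fits[[i]]$theta
    cov_o <- fits[[i]]$posterior_cov
    et <- numeric(d)
    cfull <- matrix(0, d, d)
    et[idx] <- theta_o
    cfull[idx, idx] <- cov_o
    miss <- setdiff(seq_len(d), idx)
    if (length(miss)) {
      soo <- prior$sigma[idx, idx, drop = FALSE]
      smo <- prior$sigma[miss, idx, drop = FALSE]
      a <- smo %*% solve(soo)
      et[miss] <- prior$mu[miss] + a %*% (theta_o - prior$mu[idx])
      cond <- prior$sigma[miss, miss, drop = FALSE] - a %*% t(smo)
      cfull[miss, miss] <- cond + a %*% cov_o %*% t(a)
      cfull[miss, idx] <- a %*% cov_o
      cfull[idx, miss] <- t(cfull[miss, idx, drop = FALSE])
    }
    sum_t <- sum_t + et
    sum_tt <- sum_tt + cfull + tcrossprod(et)
  }
  mu <- sum_t / n
  sigma <- sum_tt / n - tcrossprod(mu)
  list(mu = mu, sigma = (sigma + t(sigma)) / 2)
}

# ridge-regularize a covariance estimate to positive-definiteness
ensure_pd <- function(sigma, min_eig = 1e-4) {
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (min(e$values) < min_eig) {
    warn_needed <- min(e$values) < 0
    vals <- pmax(e$values, min_eig)
    sigma <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
    if (warn_needed) warnf("prior covariance ridge-regularized (min eigenvalue %.2e)",
                           min(e$values))
  }
  (sigma + t(sigma)) / 2
}

#' Likelihood-ratio screen against the chance model
#'
#' Compares the fitted model's (unpenalized) log-likelihood with the chance
#' model that assigns probability 0.5 to every choice. The statistic is
#' `2 * (data_loglik - chance_loglik)`, referred to a chi-square with 5
#' degrees of freedom per fitted session. Subjects whose fit is not better
#' than chance at `alpha` are flagged for exclusion from parameter analyses.
#'
#' @param fit a `map_fit`.
#' @param sessions the subject's sessions (same order as fitted).
#' @param alpha significance level of the screen.
#' @return a list: `statistic`, `df`, `p`, `excluded`.
#' @export
lrt_vs_chance <- function(fit, sessions, alpha = 0.05) {
  sessions <- order_sessions(sessions)
  chance <- sum(vapply(sessions, chance_loglik, numeric(1)))
  stat <- 2 * (sum(fit$data_loglik) - chance)
  df <- 5L * length(sessions)
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, excluded = p >= alpha)
}

#' Fit a whole cohort and tabulate parameters
#'
#' Convenience wrapper: groups a flat list of sessions by subject, runs
#' [em_fit_population()], applies the chance-model screen and returns a
#' per-session parameter table.
#'
#' @param sessions flat list of `twostep_session` (already QC-filtered).
#' @param ... passed to [em_fit_population()].
#' @param lrt_alpha significance level of the chance screen.
#' @return a list of class `cohort_fit`: `table` (data.frame with columns
#'   `subject_id, group, session, alpha, beta_mb, beta_mf, beta_rep,
#'   beta_consistency, data_loglik, lrt_p, excluded`), `prior`, `fits`,
#'   `lrt` (per subject).
#' @export
fit_cohort <- function(sessions, ..., lrt_alpha = 0.05) {
  ids <- vapply(sessions, `[[`, "", "subject_id")
  by_subject <- split(sessions, factor(ids, unique(ids)))
  em <- em_fit_population(by_subject, ...)
  lrt <- lapply(names(by_subject), function(id)
    lrt_vs_chance(em$fits[[id]], by_subject[[id]], alpha = lrt_alpha))
  names(lrt) <- names(by_subject)

  rows <- list()
  for (id in names(by_subject)) {
    f <- em$fits[[id]]
    ss <- order_sessions(by_subject[[id]])
    for (k in seq_along(ss)) {
      p <- f$params[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = ss[[k]]$group, session = ss[[k]]$session,
        alpha = p[["alpha"]], beta_mb = p[["beta_mb"]],
        beta_mf = p[["beta_mf"]], beta_rep = p[["beta_rep"]],
        beta_consistency = p[["beta_consistency"]],
        data_loglik = unname(f$data_loglik[k]),
        lrt_p = lrt[[id]]$p, excluded = lrt[[id]]$excluded,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), prior = em$prior,
                 fits = em$fits, lrt = lrt, em = em),
            class = "cohort_fit")
}
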