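#' Specification of a synthetic two-group, two-session cohort
#'
#' Defines the statistical structure of a simulated study: group sizes
#' (defaults 30 MUD-like, 31 control-like), group parameter distributions on
#' the unconstrained scale, the between-session correlation of individual
#' parameters, per-group follow-up attrition, per-stage omission rates, the
#' response-time model, and the deliberately pathological participants the
#' quality-control filters must catch. The default group means differ only
#' in the directions the analyses probe: the MUD-like group has a lower
#' model-free weight, a lower repetition bias and a higher second-stage
#' consistency than controls; `alpha` and the model-based weight are drawn
#' from identical distributions in both groups.
#'
#' @param n_mud,n_control group sizes.
#' @param mu_control,mu_mud length-5 unconstrained-scale means in the order
#'   (logit alpha, log beta_mb, log beta_mf, beta_rep, log beta_consistency).
#' @param sd_params length-5 between-subject standard deviations.
#' @param session_cor correlation between a subject's baseline and follow-up
#'   parameters.
#' @param attrition_mud,attrition_control probability a subject misses the
#'   follow-up session.
#' @param missing_rate per-stage omission probability for ordinary subjects.
#' @param n_high_missing,n_single_key,n_fast_rt,n_random counts of injected
#'   pathological subjects (high omission rate; near-exclusive use of one
#'   response key; abnormally fast responding; value-insensitive random
#'   chooser). The first three are caught by [apply_qc_filters()]; random
#'   choosers are caught by the chance-model likelihood-ratio screen.
#' @param pathological_missing_rate per-stage omission rate of high-missing
#'   subjects.
#' @param single_key_bias probability a single-key subject's response
#'   follows the preferred key rather than the choice.
#' @param rt_meanlog,rt_sdlog,rt_subject_sd lognormal response-time model
#'   (seconds): population location, within-subject scale, between-subject
#'   spread of locations.
#' @param fast_rt_meanlog location of fast-RT pathological subjects.
#' @param seed integer root seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mud = 30L, n_control = 31L,
                        mu_control = c(0, -0.3, 0.6, 0.8, 0.9),
                        mu_mud = c(0, -0.3, 0.0, 0.4, 1.3),
                        sd_params = c(0.8, 0.6, 0.5, 0.4, 0.4),
                        session_cor = 0.7,
                        attrition_mud = 7 / 30, attrition_control = 5 / 31,
                        missing_rate = 0.02,
                        n_high_missing = 1L, n_single_key = 1L,
                        n_fast_rt = 0L, n_random = 2L,
                        pathological_missing_rate = 0.15,
                        single_key_bias = 0.96,
                        rt_meanlog = log(0.7), rt_sdlog = 0.3,
                        rt_subject_sd = 0.15, fast_rt_meanlog = log(0.2),
                        seed = 1L) {
  if (n_mud < 2 || n_control < 2) stopf("need at least 2 subjects per group")
  if (any(c(attrition_mud, attrition_control, missing_rate,
            pathological_missing_rate, single_key_bias, session_cor) < 0) ||
      any(c(attrition_mud, attrition_control, missing_rate,
            pathological_missing_rate, single_key_bias, session_cor) > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  spec <- mget(setdiff(names(formals(cohort_spec)), "..."))
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each subject's baseline parameters from their group's distribution
#' and correlated follow-up parameters, simulates every retained session
#' with the hybrid agent on counterbalanced reward walks (the same
#' pre-determined walk set, with the subject's counterbalance permutation,
#' is reused at follow-up), injects omissions and the spec'd pathological
#' response patterns, and returns both the trial logs and the generating
#' parameters.
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @return a list of class `synthetic_cohort`: `sessions` (flat list of
#'   `twostep_session`), `truth` (data.frame of generating parameters per
#'   subject-session, with the pathology label), `metadata` (one row per
#'   subject: group, pathology, attended follow-up).
#' @export
generate_cohort <- function(spec = cohort_spec(), config = task_config()) {
  withr_seed(spec$seed, {
    base_walks <- generate_reward_walks(config, seed = derive_seed(spec$seed, 17L))
    groups <- c(rep("MUD", spec$n_mud), rep("control", spec$n_control))
    n <- length(groups)
    ids <- sprintf("S%03d", seq_len(n))

    pathology <- rep("none", n)
    pathology[assign_pathology(groups, "MUD", spec$n_random)] <- "random_chooser"
    free <- which(pathology == "none")
    take <- function(k, grp) {
      cand <- intersect(free, which(groups == grp))
      if (length(cand) < k) cand <- free
      head(cand, k)
    }
    hm <- take(spec$n_high_missing, "MUD"); pathology[hm] <- "high_missing"
    free <- setdiff(free, hm)
    sk <- take(spec$n_single_key, "control"); pathology[sk] <- "single_key"
    free <- setdiff(free, sk)
    fr <- take(spec$n_fast_rt, "MUD"); pathology[fr] <- "fast_rt"

    sessions <- list()
    truth <- list()
    meta <- list()
    for (i in seq_len(n)) {
      grp <- groups[i]
      mu <- if (grp == "MUD") spec$mu_mud else spec$mu_control
      z1 <- rnorm(5)
      z2 <- spec$session_cor * z1 + sqrt(1 - spec$session_cor^2) * rnorm(5)
      theta1 <- mu + spec$sd_params * z1
      theta2 <- mu + spec$sd_params * z2
      if (pathology[i] == "random_chooser") {
        theta1[2:5] <- theta2[2:5] <- c(-20, -20, 0, -20)
      }
      attended <- runif(1) >= if (grp == "MUD") spec$attrition_mud else
        spec$attrition_control
      rt_loc <- if (pathology[i] == "fast_rt") spec$fast_rt_meanlog else
        rnorm(1, spec$rt_meanlog, spec$rt_subject_sd)
      miss <- if (pathology[i] == "high_missing")
        spec$pathological_missing_rate else spec$missing_rate
      bias <- if (pathology[i] == "single_key") spec$single_key_bias else 0

      # counterbalance round-robin within each group, so the two groups
      # receive matched permutation distributions
      cb <- (sum(groups[seq_len(i)] == grp) - 1L) %% 8L
      walks <- counterbalance_walks(base_walks, cb)
      cfg <- config; cfg$counterbalance_id <- cb
      for (sess in c("baseline", if (attended) "followup")) {
        theta <- if (sess == "baseline") theta1 else theta2
        params <- to_natural(theta)
        sessions[[length(sessions) + 1L]] <- simulate_agent(
          params, walks, cfg, subject_id = ids[i], group = grp,
          session = sess, missing_rate = miss, rt_meanlog = rt_loc,
          rt_sdlog = spec$rt_sdlog, side_bias = bias)
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = ids[i], group = grp, session = sess,
          pathology = pathology[i], alpha = params[["alpha"]],
          beta_mb = params[["beta_mb"]], beta_mf = params[["beta_mf"]],
          beta_rep = params[["beta_rep"]],
          beta_consistency = params[["beta_consistency"]],
          stringsAsFactors = FALSE)
      }
      meta[[i]] <- data.frame(subject_id = ids[i], group = grp,
                              pathology = pathology[i],
                              attended_followup = attended,
                              counterbalance_id = cb,
                              stringsAsFactors = FALSE)
    }
    structure(list(sessions = sessions, truth = do.call(rbind, truth),
                   metadata = do.call(rbind, meta), spec = spec),
              class = "synthetic_cohort")
  })
}

assign_pathology <- function(groups, grp, k) {
  which(groups == grp)[seq_len(min(k, sum(groups == grp)))]
}

#' Quality-control filters for task disengagement
#'
#' Flags participant-sessions that (a) miss more than `missing_threshold` of
#' trials (a trial counts as missing if either stage's response was
#' omitted), (b) respond with the same key on more than `same_key_threshold`
#' of responses pooled across both stages, or (c) respond more than
#' `rt_sd_threshold` standard deviations faster than the other participants
#' (each session's mean response time is compared with the mean and SD of
#' all *other* subjects' session means; a degenerate zero-SD distribution
#' flags nobody).
#'
#' @param sessions flat list of `twostep_session` (at least 3 for the
#'   response-time rule).
#' @param missing_threshold,same_key_threshold,rt_sd_threshold rule
#'   parameters.
#' @return a data.frame of class `qc_report`: one row per session with the
#'   computed metrics, individual flags, the overall `excluded` flag and a
#'   semicolon-separated `reasons` string.
#' @export
apply_qc_filters <- function(sessions, missing_threshold = 0.10,
                             same_key_threshold = 0.95, rt_sd_threshold = 2) {
  rows <- lapply(sessions, function(s) {
    tr <- s$trials
    missing_frac <- mean(is.na(tr$c1) | is.na(tr$c2))
    keys <- c(tr$side1[!is.na(tr$side1)], tr$side2[!is.na(tr$side2)])
    same_key_frac <- if (length(keys)) max(table(factor(keys, c("left", "right")))) /
      length(keys) else NA_real_
    rts <- c(tr$rt1, tr$rt2)
    data.frame(subject_id = s$subject_id, session = s$session,
               group = s$group, n_trials = nrow(tr),
               missing_frac = missing_frac, same_key_frac = same_key_frac,
               mean_rt = if (all(is.na(rts))) NA_real_ else mean(rts, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)

  rep$flag_missing <- rep$missing_frac > missing_threshold
  rep$flag_same_key <- !is.na(rep$same_key_frac) &
    rep$same_key_frac > same_key_threshold

  # leave-one-subject-out response-time screen
  rep$flag_fast_rt <- FALSE
  if (nrow(rep) >= 3 && any(!is.na(rep$mean_rt))) {
    for (i in seq_len(nrow(rep))) {
      if (is.na(rep$mean_rt[i])) next
      others <- rep$mean_rt[rep$subject_id != rep$subject_id[i]]
      others <- others[!is.na(others)]
      if (length(others) < 2) next
      s <- sd(others)
      if (s > 0 && rep$mean_rt[i] < mean(others) - rt_sd_threshold * s) {
        rep$flag_fast_rt[i] <- TRUE
      }
    }
  }

  rep$excluded <- rep$flag_missing | rep$flag_same_key | rep$flag_fast_rt
  rep$reasons <- apply(rep[, c("flag_missing", "flag_same_key", "flag_fast_rt")],
                       1, function(f) paste(c("missing_trials", "same_key",
                                              "fast_rt")[f], collapse = ";"))
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Simulate methamphetamine-use variables linked to parameters
#'
#' Builds an Aim-2-style covariate table for the MUD-like group: each use
#' variable is a monotone function of one generating parameter plus noise,
#' together with a days-since-last-use covariate, so correlation and
#' regression analyses have a known signal to find.
#'
#' @param truth the `truth` table of a [generate_cohort()] result (baseline
#'   rows of the MUD group are used).
#' @param link named list mapping use-variable names to parameter names.
#' @param noise_sd residual noise on the standardized scale.
#' @return a data.frame with `subject_id`, `days_since_last_use` and one
#'   column per use variable. Uses the current RNG stream.
#' @export
simulate_use_table <- function(truth,
                               link = list(frequency_of_use = "beta_consistency",
                                           sds = "beta_mf"),
                               noise_sd = 1) {
  tb <- truth[truth$group == "MUD" & truth$session == "baseline" &
                truth$pathology == "none", ]
  out <- data.frame(subject_id = tb$subject_id,
                    days_since_last_use = round(rlnorm(nrow(tb), log(20), 0.7)),
                    stringsAsFactors = FALSE)
  for (v in names(link)) {
    x <- tb[[link[[v]]]]
    out[[v]] <- as.numeric(scale(x)) + rnorm(nrow(tb), 0, noise_sd)
  }
  out
}
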