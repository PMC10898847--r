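#' Default generating distribution for recovery studies
#'
#' Broad, weakly structured parameter draws: `alpha` uniform on
#' (0.05, 0.95); `beta_mb`, `beta_mf` and `beta_consistency` lognormal with
#' log-scale mean 0 and SD 0.8; `beta_rep` normal with mean 0.5 and SD 0.7.
#'
#' @param n number of parameter sets.
#' @return a data.frame of natural-space parameters, one row per subject.
#'   Uses the current RNG stream.
#' @export
draw_recovery_params <- function(n) {
  data.frame(alpha = runif(n, 0.05, 0.95),
             beta_mb = exp(rnorm(n, 0, 0.8)),
             beta_mf = exp(rnorm(n, 0, 0.8)),
             beta_rep = rnorm(n, 0.5, 0.7),
             beta_consistency = exp(rnorm(n, 0, 0.8)))
}

#' Parameter-recovery experiment
#'
#' Simulates sessions from known parameters, refits them with the full
#' hierarchical pipeline and correlates recovered against generating values
#' parameter by parameter. Each of `n_datasets` replicate datasets is an
#' independently simulated session per subject on the same counterbalanced
#' walks; recovered values are averaged over datasets per subject before
#' correlating (per-dataset pooled correlations are reported alongside).
#'
#' @param n_subjects number of simulated participants.
#' @param n_datasets replicate datasets per subject.
#' @param param_source a data.frame of generating parameters (columns as
#'   [draw_recovery_params()]) or a function `f(n)` producing one; defaults
#'   to [draw_recovery_params()].
#' @param config a [task_config()].
#' @param seed integer seed controlling the whole experiment.
#' @param ... passed to [em_fit_population()] (restart budget, tolerances).
#' @return a list of class `recovery_report`: `correlations` (data.frame
#'   with Pearson and Spearman correlations per parameter, averaged and
#'   pooled), `truth`, `recovered`, `n_failed`, plus the experiment sizes.
#' @export
run_recovery <- function(n_subjects = 60L, n_datasets = 5L,
                         param_source = NULL, config = task_config(),
                         seed = 1L, ...) {
  if (n_subjects < 10) stopf("need at least 10 subjects for a meaningful correlation")
  withr_seed(seed, {
    truth <- if (is.data.frame(param_source)) param_source
      else if (is.function(param_source)) param_source(n_subjects)
      else draw_recovery_params(n_subjects)
    n_subjects <- nrow(truth)
    ids <- sprintf("R%03d", seq_len(n_subjects))
    base_walks <- generate_reward_walks(config, seed = derive_seed(seed, 5L))

    rec_list <- vector("list", n_datasets)
    n_failed <- 0L
    for (d in seq_len(n_datasets)) {
      by_subject <- list()
      for (i in seq_len(n_subjects)) {
        cfg <- config; cfg$counterbalance_id <- (i - 1L) %% 8L
        walks <- counterbalance_walks(base_walks, cfg$counterbalance_id)
        params <- parameter_set(truth$alpha[i], truth$beta_mb[i],
                                truth$beta_mf[i], truth$beta_rep[i],
                                truth$beta_consistency[i])
        by_subject[[ids[i]]] <- list(simulate_agent(params, walks, cfg,
                                                    subject_id = ids[i]))
      }
      em <- em_fit_population(by_subject, ...)
      rec <- do.call(rbind, lapply(ids, function(id) {
        f <- em$fits[[id]]
        if (is.null(f)) return(NULL)
        as.data.frame(as.list(unclass(f$params[[1]])))
      }))
      n_failed <- n_failed + (n_subjects - nrow(rec))
      rec$subject_id <- ids[seq_len(nrow(rec))]
      rec$dataset <- d
      rec_list[[d]] <- rec
    }
    pooled <- do.call(rbind, rec_list)
    avg <- stats::aggregate(pooled[param_names],
                            by = list(subject_id = pooled$subject_id), mean)
    avg <- avg[match(ids, avg$subject_id), ]

    truth_pooled <- truth[match(pooled$subject_id, ids), ]
    correlations <- do.call(rbind, lapply(param_names, function(pn) {
      data.frame(parameter = pn,
                 pearson = cor(truth[[pn]], avg[[pn]]),
                 spearman = cor(truth[[pn]], avg[[pn]], method = "spearman"),
                 pearson_pooled = cor(truth_pooled[[pn]], pooled[[pn]]),
                 stringsAsFactors = FALSE)
    }))
    structure(list(correlations = correlations, truth = truth,
                   recovered = avg, pooled = pooled, n_subjects = n_subjects,
                   n_datasets = n_datasets, seed = seed, n_failed = n_failed),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d subjects x %d dataset(s)\n",
              x$n_subjects, x$n_datasets))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
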