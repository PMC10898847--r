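#' Pipeline stages with file input/output
#'
#' Thin orchestration layer over the simulation, fitting, recovery and
#' analysis functions: each stage reads/writes the package's CSV dialects
#' and drops a JSON manifest (configuration, seed, package version) next to
#' its outputs so every file is regenerable from its manifest alone. These
#' functions back the command-line script installed at
#' `system.file("cli", "twostep.R", package = "twosteprl")`.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @param seed integer seed for the stage.
#' @return `pipeline_simulate` writes `trials.csv`, `metadata.csv`,
#'   `truth.csv` and returns their paths invisibly.
#' @rdname pipeline
#' @export
pipeline_simulate <- function(out_dir, spec = cohort_spec(),
                              config = task_config(), seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, config)
  write_session_csv(cohort$sessions, file.path(out_dir, "trials.csv"))
  write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_manifest(out_dir, "simulate", c(unclass(spec),
                                        list(n_trials = config$n_trials)))
  invisible(file.path(out_dir, c("trials.csv", "metadata.csv", "truth.csv")))
}

#' @param trial_log path to a trial-log CSV.
#' @param n_starts,n_fits multi-start budget (see [map_fit_subject()]).
#' @param qc apply [apply_qc_filters()] before fitting.
#' @return `pipeline_fit` writes `parameters.csv` (and `qc_report.csv`) and
#'   returns the parameter table invisibly; the table is empty (but valid)
#'   when every session fails QC.
#' @rdname pipeline
#' @export
pipeline_fit <- function(trial_log, out_dir, n_starts = 10L, n_fits = 50L,
                         qc = TRUE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- read_session_csv(trial_log)
  if (qc && length(sessions) >= 3) {
    rep <- apply_qc_filters(sessions)
    write.csv(rep, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
    keep <- !rep$excluded
    sessions <- sessions[keep]
  }
  empty <- data.frame(subject_id = character(), group = character(),
                      session = character(), alpha = numeric(),
                      beta_mb = numeric(), beta_mf = numeric(),
                      beta_rep = numeric(), beta_consistency = numeric(),
                      data_loglik = numeric(), lrt_p = numeric(),
                      excluded = logical())
  tab <- if (length(sessions) >= 2) {
    withr_seed(seed, fit_cohort(sessions, n_starts = n_starts,
                                n_fits = n_fits)$table)
  } else {
    message("fewer than 2 sessions passed QC; writing empty parameter table")
    empty
  }
  write.csv(tab, file.path(out_dir, "parameters.csv"), row.names = FALSE)
  write_manifest(out_dir, "fit", list(trial_log = trial_log, seed = seed,
                                      n_starts = n_starts, n_fits = n_fits,
                                      qc = qc))
  invisible(tab)
}

#' @param n_subjects,n_datasets recovery sizes (see [run_recovery()]).
#' @return `pipeline_recover` writes `recovery.csv` and returns the report
#'   invisibly.
#' @rdname pipeline
#' @export
pipeline_recover <- function(out_dir, n_subjects = 60L, n_datasets = 1L,
                             config = task_config(), seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- run_recovery(n_subjects = n_subjects, n_datasets = n_datasets,
                      config = config, seed = seed, ...)
  write.csv(rep$correlations, file.path(out_dir, "recovery.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "recover", list(n_subjects = n_subjects,
                                          n_datasets = n_datasets,
                                          seed = seed))
  invisible(rep)
}

#' @param parameter_table path to a `parameters.csv` from `pipeline_fit`.
#' @param longitudinal fit the two-session stay model.
#' @return `pipeline_analyze` writes `stay_regression.csv`,
#'   `group_tests.csv` (and `anova.csv` for longitudinal data) and returns
#'   the results invisibly.
#' @rdname pipeline
#' @export
pipeline_analyze <- function(trial_log, parameter_table, out_dir,
                             longitudinal = FALSE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- read_session_csv(trial_log)
  records <- code_stay_records(sessions)
  if (!longitudinal) records <- records[records$time == "baseline", ]
  glmm <- fit_stay_glmm(records, longitudinal = longitudinal)
  write.csv(glmm$terms, file.path(out_dir, "stay_regression.csv"),
            row.names = FALSE)

  tab <- read.csv(parameter_table, stringsAsFactors = FALSE)
  results <- list(glmm = glmm)
  if (nrow(tab)) {
    base <- tab[tab$session == "baseline" & !tab$excluded, ]
    tests <- lapply(param_names, function(pn)
      compare_parameter_groups(base, pn))
    results$group_tests <- do.call(rbind, lapply(tests, function(x)
      data.frame(parameter = x$parameter, U = x$statistic, p = x$p,
                 direction = x$direction, stringsAsFactors = FALSE)))
    write.csv(results$group_tests, file.path(out_dir, "group_tests.csv"),
              row.names = FALSE)
    if (longitudinal && any(tab$session == "followup")) {
      results$anovas <- do.call(rbind, lapply(param_names, function(pn) {
        a <- anova_group_by_time(tab[!tab$excluded, ], pn)
        a$parameter <- pn
        a
      }))
      write.csv(results$anovas, file.path(out_dir, "anova.csv"),
                row.names = FALSE)
    }
  }
  write_manifest(out_dir, "analyze", list(trial_log = trial_log,
                                          parameter_table = parameter_table,
                                          longitudinal = longitudinal,
                                          seed = seed))
  invisible(results)
}

#' @return `run_pipeline` executes simulate, fit and analyze in order under
#'   one root seed and returns the collected outputs invisibly.
#' @rdname pipeline
#' @export
run_pipeline <- function(out_dir, spec = cohort_spec(),
                         config = task_config(), seed = 1L,
                         n_starts = 10L, n_fits = 50L,
                         longitudinal = FALSE) {
  spec$seed <- derive_seed(seed, 1L)
  pipeline_simulate(file.path(out_dir, "simulate"), spec, config)
  tab <- pipeline_fit(file.path(out_dir, "simulate", "trials.csv"),
                      file.path(out_dir, "fit"), n_starts = n_starts,
                      n_fits = n_fits, seed = derive_seed(seed, 2L))
  res <- pipeline_analyze(file.path(out_dir, "simulate", "trials.csv"),
                          file.path(out_dir, "fit", "parameters.csv"),
                          file.path(out_dir, "analyze"),
                          longitudinal = longitudinal,
                          seed = derive_seed(seed, 3L))
  invisible(list(parameters = tab, analysis = res))
}

write_manifest <- function(out_dir, stage, config) {
  manifest <- list(stage = stage, config = config,
                   package_version = as.character(packageVersion("twosteprl")),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}
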