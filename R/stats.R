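#' Code stay/switch regression records from trial logs
#'
#' For every pair of consecutive valid trials, emits one row recording
#' whether the first-stage choice was repeated (`stay`, 0/1), whether the
#' previous trial was rewarded (`prev_win`, effect-coded -1/+1) and whether
#' its transition was common (`prev_transition`, -1 rare / +1 common),
#' together with subject, group and time labels. Pairs that span a missing
#' or incomplete trial are dropped, as are non-adjacent trial pairs.
#'
#' @param sessions flat list of `twostep_session` (QC-passed).
#' @return a data.frame with columns `subject_id`, `group`, `time`, `stay`,
#'   `prev_win`, `prev_transition`.
#' @export
code_stay_records <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    tr <- s$trials
    prev_complete <- !is.na(tr$c1) & !is.na(tr$reward) & !is.na(tr$transition)
    cur_valid <- !is.na(tr$c1)
    i <- which(prev_complete[-nrow(tr)] & cur_valid[-1])  # trial t-1 index
    if (!length(i)) return(NULL)
    data.frame(
      subject_id = s$subject_id, group = s$group, time = s$session,
      stay = as.integer(tr$c1[i + 1L] == tr$c1[i]),
      prev_win = ifelse(tr$reward[i] == 1L, 1, -1),
      prev_transition = ifelse(tr$transition[i] == "common", 1, -1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mixed logistic regression of stay behaviour
#'
#' Fits the stay/switch model with a logit link and the `bobyqa` optimizer.
#' The baseline model is the full factorial of Previous Win, Previous
#' Transition and Group; the longitudinal model adds Time and all its
#' interactions. By default the random-effects structure is a per-subject
#' intercept plus Previous Win and Previous Transition slopes (plus a Time
#' slope in the longitudinal model): with only a random intercept, real
#' between-subject variation in reward sensitivity deflates the standard
#' errors of the between-subject terms and inflates their type-I error,
#' so the slope terms are kept unless `random_slopes = FALSE` (which
#' reproduces the intercept-only structure some published analyses use).
#' Previous Win and Previous Transition are
#' effect-coded -1/+1; Group is treatment-coded control = 0, MUD = 1 and
#' Time baseline = 0, follow-up = 1. Bernoulli rows are aggregated to
#' binomial counts per subject-by-cell before fitting (an equivalent
#' likelihood, considerably faster).
#'
#' @param records a [code_stay_records()] data.frame.
#' @param longitudinal if `TRUE`, fit the two-session model with Time.
#' @param random_slopes include per-subject Previous Win / Previous
#'   Transition random slopes (default) or a random intercept only.
#' @param aggregate aggregate to binomial counts (default) or fit raw rows.
#' @return a list of class `stay_glmm`: `model` (the `glmerMod`), `terms`
#'   (data.frame with log-odds estimates, SEs, z, p, odds ratios and 95%
#'   CIs), `converged`, `n_obs` (Bernoulli trials), `ranef_var`.
#' @export
fit_stay_glmm <- function(records, longitudinal = FALSE,
                          random_slopes = TRUE, aggregate = TRUE) {
  groups <- unique(records$group)
  if (length(groups) > 1 && min(table(records$group[!duplicated(records$subject_id)])) < 2) {
    stopf("need at least 2 subjects per group")
  }
  if (length(unique(records$stay)) < 2) {
    stopf("degenerate outcome: all stay values are %d (complete separation)",
          records$stay[1])
  }
  d <- data.frame(
    stay = records$stay,
    prev_win = records$prev_win,
    prev_transition = records$prev_transition,
    group = as.numeric(records$group == "MUD"),
    time = as.numeric(records$time == "followup"),
    subject_id = records$subject_id,
    stringsAsFactors = FALSE)

  slopes <- if (random_slopes) " + prev_win + prev_transition" else ""
  fixed <- "prev_win * prev_transition"
  if (length(unique(d$group)) > 1) fixed <- paste0(fixed, " * group")
  if (longitudinal) {
    if (length(unique(d$time)) < 2) stopf("longitudinal model needs both sessions")
    fixed <- paste0(fixed, " * time")
    random <- paste0("(1 + time", slopes, " | subject_id)")
  } else {
    random <- paste0("(1", slopes, " | subject_id)")
  }

  if (aggregate) {
    cell <- interaction(d$subject_id, d$prev_win, d$prev_transition, d$time,
                        drop = TRUE)
    agg <- do.call(rbind, lapply(split(d, cell), function(b) {
      b1 <- b[1, ]; b1$n_stay <- sum(b$stay); b1$n_tot <- nrow(b); b1
    }))
    f <- as.formula(paste("cbind(n_stay, n_tot - n_stay) ~", fixed, "+", random))
    m <- lme4::glmer(f, data = agg, family = stats::binomial("logit"),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  } else {
    f <- as.formula(paste("stay ~", fixed, "+", random))
    m <- lme4::glmer(f, data = d, family = stats::binomial("logit"),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  }

  co <- summary(m)$coefficients
  terms <- data.frame(
    term = rownames(co), estimate = co[, 1], std_error = co[, 2],
    z = co[, 3], p = co[, 4], or = exp(co[, 1]),
    or_lo = exp(co[, 1] - qnorm(0.975) * co[, 2]),
    or_hi = exp(co[, 1] + qnorm(0.975) * co[, 2]),
    row.names = NULL, stringsAsFactors = FALSE)
  msgs <- m@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  structure(list(model = m, terms = terms,
                 converged = length(msgs) == 0,
                 n_obs = nrow(d),
                 ranef_var = as.data.frame(lme4::VarCorr(m))),
            class = "stay_glmm")
}

#' Marginal-means post-hoc contrasts for group-by-reward effects
#'
#' Computes estimated marginal mean stay log-odds at previous-win = -1 and
#' +1 for each group (with the remaining predictors at their neutral value),
#' then tests the family of pairwise group-by-reward contrasts with a Tukey
#' multiplicity adjustment. Odds ratios are reported on the response
#' contrast scale.
#'
#' @param fit a [fit_stay_glmm()] result.
#' @return a list: `emmeans` (marginal means grid), `contrasts` (data.frame
#'   with odds ratios, adjusted p-values and 95% CIs).
#' @export
marginal_means_posthoc <- function(fit) {
  if (!any(grepl("group", fit$terms$term))) {
    stopf("model contains no group term; contrasts are not estimable")
  }
  em <- emmeans::emmeans(fit$model, ~ group * prev_win,
                         at = list(group = c(0, 1), prev_win = c(-1, 1),
                                   prev_transition = 0))
  ctr <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  cs <- summary(ctr, infer = TRUE)
  out <- data.frame(contrast = as.character(cs$contrast),
                    estimate = cs$estimate, se = cs$SE,
                    or = exp(cs$estimate),
                    or_lo = exp(cs$estimate - qnorm(0.975) * cs$SE),
                    or_hi = exp(cs$estimate + qnorm(0.975) * cs$SE),
                    p_adj = cs$p.value, stringsAsFactors = FALSE)
  list(emmeans = summary(em), contrasts = out)
}

#' Rank-sum comparison of a parameter between groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, exact for small
#' tie-free samples. The direction reports which group has the larger
#' median.
#'
#' @param param_table a [fit_cohort()] parameter table (or any data.frame
#'   with `group` and the parameter column); LRT-excluded rows should be
#'   removed by the caller.
#' @param parameter column name to test.
#' @param groups length-2 character vector of group labels.
#' @return a list of class `group_test`: `parameter`, `statistic` (U), `p`,
#'   `direction`, group medians.
#' @export
compare_parameter_groups <- function(param_table, parameter,
                                     groups = c("MUD", "control")) {
  x <- param_table[[parameter]][param_table$group == groups[1]]
  y <- param_table[[parameter]][param_table$group == groups[2]]
  if (length(x) < 3 || length(y) < 3) stopf("need at least 3 per group")
  if (length(unique(c(x, y))) == 1) {
    warnf("constant data for %s; no group difference detectable", parameter)
    return(structure(list(parameter = parameter, statistic = length(x) *
                            length(y) / 2, p = 1, direction = "none",
                          median_1 = median(x), median_2 = median(y),
                          groups = groups), class = "group_test"))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = (length(x) < 50 &&
                                                      length(y) < 50)))
  structure(list(parameter = parameter, statistic = unname(wt$statistic),
                 p = wt$p.value,
                 direction = if (median(x) > median(y))
                   paste(groups[1], ">", groups[2]) else
                     paste(groups[1], "<", groups[2]),
                 median_1 = median(x), median_2 = median(y),
                 groups = groups), class = "group_test")
}

#' Mixed-design Group-by-Time ANOVA for one parameter
#'
#' 2 (Group, between) x 2 (Time, within) analysis of variance on a fitted
#' parameter, using only subjects with both sessions (others are dropped
#' with a message).
#'
#' @param param_table per-session parameter table with `subject_id`,
#'   `group`, `session` and the parameter column.
#' @param parameter column name to analyse.
#' @return a data.frame of class `anova_gxt`: one row per effect (`group`,
#'   `time`, `group:time`) with F, df and p.
#' @export
anova_group_by_time <- function(param_table, parameter) {
  tab <- param_table[, c("subject_id", "group", "session", parameter)]
  counts <- table(tab$subject_id)
  keep <- names(counts)[counts == 2]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped)) {
    message(sprintf("dropping %d subject(s) without both sessions: %s",
                    length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  tab <- tab[tab$subject_id %in% keep, ]
  if (length(unique(tab$group)) < 2) stopf("need both groups")
  d <- data.frame(y = tab[[parameter]], group = factor(tab$group),
                  time = factor(tab$session), subject = factor(tab$subject_id))
  m <- aov(y ~ group * time + Error(subject / time), data = d)
  sm <- summary(m)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: subject:time"]][[1]]
  pick <- function(stratum, term) {
    i <- trimws(rownames(stratum)) == term
    data.frame(effect = term, df1 = stratum$Df[i],
               df2 = stratum$Df[trimws(rownames(stratum)) == "Residuals"],
               F = stratum$`F value`[i], p = stratum$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(between, "group"), pick(within, "time"),
               pick(within, "group:time"))
  class(out) <- c("anova_gxt", "data.frame")
  out
}

#' Correlations and regressions between parameters and use variables
#'
#' For the MUD-like group: Spearman correlations between every parameter
#' and every use variable, then for each use variable an ordinary
#' least-squares regression of the (mean-centred) variable on the five
#' parameters plus a days-since-last-use covariate, with variance-inflation
#' factors. Configurable outlier rules (per-variable inclusive ranges) are
#' applied as complete-case exclusions before each analysis.
#'
#' @param param_table baseline parameter table (LRT-excluded rows removed by
#'   the caller), MUD rows are selected by `group`.
#' @param use_table data.frame with `subject_id`, the covariate and use
#'   variables.
#' @param covariate column name of the covariate entered in every
#'   regression.
#' @param outlier_rules named list `variable = c(lo, hi)`; rows outside the
#'   range are dropped for analyses involving that variable.
#' @return a list of class `use_correlations`: `spearman` (correlation
#'   matrix), `regressions` (per use variable: coefficients, F, df, R2, p,
#'   VIFs, n).
#' @export
correlate_params_use <- function(param_table, use_table,
                                 covariate = "days_since_last_use",
                                 outlier_rules = list()) {
  pt <- param_table[param_table$group == "MUD", c("subject_id", param_names)]
  d <- merge(pt, use_table, by = "subject_id")
  use_vars <- setdiff(names(use_table), c("subject_id", covariate))
  for (v in names(outlier_rules)) {
    r <- outlier_rules[[v]]
    d[[v]][!is.na(d[[v]]) & (d[[v]] < r[1] | d[[v]] > r[2])] <- NA
  }
  num_cols <- c(param_names, covariate, use_vars)
  spearman <- cor(d[num_cols], use = "pairwise.complete.obs",
                  method = "spearman")

  regressions <- lapply(use_vars, function(v) {
    dd <- d[complete.cases(d[c(param_names, covariate, v)]), ]
    n_pred <- length(param_names) + 1L
    if (nrow(dd) < n_pred + 2L) {
      stopf("only %d complete cases for %s; need at least %d",
            nrow(dd), v, n_pred + 2L)
    }
    dd$.y <- dd[[v]] - mean(dd[[v]])
    f <- as.formula(paste(".y ~", paste(c(param_names, covariate),
                                        collapse = " + ")))
    m <- lm(f, data = dd)
    sm <- summary(m)
    fstat <- sm$fstatistic
    list(variable = v, n = nrow(dd),
         coefficients = as.data.frame(sm$coefficients),
         r_squared = sm$r.squared,
         f = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
         p = pf_upper(fstat),
         vif = car::vif(m))
  })
  names(regressions) <- use_vars
  structure(list(spearman = spearman, regressions = regressions),
            class = "use_correlations")
}

pf_upper <- function(fstat) {
  stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
}
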