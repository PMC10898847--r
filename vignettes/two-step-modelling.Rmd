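---
title: "Modelling model-based and model-free choice in the two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling model-based and model-free choice in the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosteprl)
```

## The task and the scientific question

The two-step task is a sequential decision problem used to separate two
valuation systems. On each trial the participant first chooses between two
options (spaceships); each option leads with probability 0.7 to its *common*
second-stage state and with probability 0.3 to the other, *rare*, state
(two planets). In the visited state the participant chooses between two
options (aliens) whose reward probabilities drift across trials as
independent Gaussian random walks, so there is always something left to
learn. A *model-based* (MB) chooser evaluates first-stage options
prospectively through the transition structure; a *model-free* (MF) chooser
caches past outcomes of first-stage choices directly. The two systems make
different predictions about *staying* — repeating the previous first-stage
choice — after rewarded versus unrewarded trials and after common versus
rare transitions: MF control shows a main effect of previous reward, MB
control shows a reward-by-transition interaction.

`twosteprl` packages the full analysis chain used in clinical comparisons
of these systems (for instance between people with a stimulant-use disorder
and matched controls): task simulation, a hybrid MB/MF learning model and
its likelihood, hierarchical empirical-Bayes estimation, parameter
recovery, quality-control filters, and the stay/switch statistics.

## The hybrid model

Five parameters govern behaviour (`parameter_set()`):

* `alpha` in [0, 1] — a shared learning *and* forgetting rate. The chosen
  second-stage option updates as `q' = (1 - alpha) * q + r`; every unchosen
  value decays by `(1 - alpha)` at the end of the trial.
* `beta_mb` ≥ 0 — weight on the MB first-stage value, the maximum
  second-stage value in the option's common state.
* `beta_mf` ≥ 0 — weight on the MF first-stage value. After each complete
  trial the chosen first-stage option's MF value is replaced by the
  just-updated value of the chosen second-stage option, so first-stage
  options acquire value without reference to the transition structure.
* `beta_rep` — a value-independent bias toward (or, if negative, against)
  repeating the previous first-stage choice.
* `beta_consistency` ≥ 0 — the second-stage inverse temperature.

Both stages choose through softmax rules. All values start at zero, and the
repetition indicator is zero for both options on the first trial. One
bookkeeping subtlety deserves note: the first-stage MF "decay" rule and the
assignment rule both touch the chosen option's entry. We keep a single
first-stage MF table in which the assignment *overwrites* the chosen entry
and the decay applies to the unchosen one — the only reading under which
learning, assignment and forgetting are all simultaneously operative. A
second subtlety is directionality: a *larger* `alpha` discards the old
value faster at the update and forgets unchosen values faster; prose
descriptions of this parameter family sometimes state the direction the
other way around, so we document the algebra rather than the label.

Missing responses are handled conservatively: a missing first-stage
response voids the whole trial (no likelihood term, no learning); a missing
second-stage response keeps the first-stage term but updates nothing,
because no outcome was observed.

The likelihood is implemented twice: a compiled recursion used everywhere,
and a deliberately naive per-trial R composition of the exported single-step
operations (`session_loglik(..., method = "reference")`). The two agree to
`1e-10` on random sessions, and the betas-zero closed form
`2n log(0.5)` anchors both.

## Fitting: empirical-Bayes MAP

Parameters are estimated on an unconstrained scale (logistic transform for
`alpha`, log for the three non-negative betas, identity for `beta_rep`).
Each subject's sessions are fitted jointly: the parameter vector stacks 5
entries per session, and a Gaussian population prior over that stacked
vector — full covariance, so between-session correlation is captured — is
estimated from the whole cohort by expectation-maximization
(`em_fit_population()`). The E-step computes each subject's maximum a
posteriori estimate by multi-start BFGS (starts drawn from the current
prior; `n_fits` runs over `n_starts` distinct start points, defaults 50
and 10) with a Laplace posterior covariance from the numerical Hessian;
the M-step re-estimates the prior mean and covariance, with subjects who
only completed one session contributing through the conditional Gaussian
expectation of their missing block. Iteration stops when the prior mean
moves less than `tol` (default 0.01 on the unconstrained scale). Numerical
safeguards: softmax with max-subtraction, probabilities floored at `1e-12`,
objective guarded against `|theta| > 50`, covariance eigenvalues floored at
`1e-4` (diagonal-only mode available via `diagonal = TRUE`).

Each fitted subject is screened against a chance model that assigns
probability 0.5 to every choice: the likelihood-ratio statistic
`2 * (loglik - chance)` is referred to a chi-square with 5 degrees of
freedom per fitted session, and subjects not better than chance at
`alpha = 0.05` are flagged and excluded from parameter-level analyses
(they remain in the behavioural regressions). The degrees of freedom
ignore the boundary constraints on the betas, which makes the screen
slightly conservative — a documented caveat, acceptable for a screen.

## Parameter recovery

`run_recovery()` draws generating parameters from broad distributions
(`alpha` uniform on (0.05, 0.95); log-normal betas, log-scale SD 0.8;
`beta_rep` normal with mean 0.5, SD 0.7), simulates 200-trial sessions,
refits them with the full hierarchical pipeline and correlates recovered
against generating values. Replicate datasets per subject are averaged
before correlating (pooled per-dataset correlations are reported
alongside); the default is 5 replicates, trading the idea of many
replicates per subject against desk-scale runtime. With a single replicate
the `alpha` correlation is noise-limited to roughly 0.93–0.95 under these
broad generating draws — single 200-trial sessions carry only so much
information — and with 5 replicates it reaches roughly 0.96, with every
parameter above 0.8. Recovery from *empirically clustered* parameter sets
(as when recovering from a fitted cohort) is easier than from these
deliberately broad draws, so these figures are conservative.

## The synthetic cohort and what it does (and does not) emulate

`generate_cohort()` produces a two-group, two-session cohort with known
ground truth. Group parameter distributions live on the unconstrained
scale; the defaults differ only in the three directions group comparisons
in this literature probe — the clinical-like group has a lower MF weight,
a lower repetition bias and a higher second-stage consistency (shifts of
roughly one between-subject SD), with `alpha` and the MB weight drawn
identically in both groups. Follow-up parameters correlate 0.7 with
baseline; follow-up attrition defaults to 7/30 and 5/31; ordinary subjects
omit each response with probability 0.02. Reward walks are pre-determined
once per cohort and counterbalanced by permuting the four walk columns,
assigned round-robin *within* each group (so the groups receive matched
permutation distributions — assigning across the pooled cohort leaks a
systematic group difference through the shared walks) and reused at
follow-up. Response times are lognormal with subject-level locations.

Deliberate pathologies exercise the quality-control rules: a high-omission
subject, a single-key responder (responses follow a preferred key rather
than the choice with probability 0.96), optionally an abnormally fast
responder, and two value-insensitive random choosers that only the
chance-model screen can catch. `apply_qc_filters()` implements the three
disengagement rules: more than 10% of trials missing; more than 95% of
responses on one key pooled across stages (strict inequality, so 96% is
flagged and 94% is not); and a session mean response time more than 2 SDs
faster than the other participants' means (leave-one-subject-out; a
zero-spread reference flags nobody). The 2-SD rule is a tail rule: on any
continuous RT spread it can flag the fastest ordinary participant, so its
false-flag rate is small but not zero by construction.

What the generator does *not* emulate: real reaction-time dynamics
(post-error slowing, fatigue), within-session parameter drift,
non-stationary engagement, clinical covariates beyond simple monotone
links (`simulate_use_table()`), or systematic (non-random) attrition.
Passing tests on this cohort therefore validate the estimation and
statistical machinery, not the psychological realism of any particular
dataset.

## Stay/switch statistics

`code_stay_records()` converts trial logs into one row per consecutive
valid trial pair: `stay` (0/1), `prev_win` and `prev_transition` effect
coded -1/+1; pairs spanning an omission are dropped. `fit_stay_glmm()`
fits the mixed logistic regression with a logit link and the `bobyqa`
optimizer: at baseline the full factorial of Previous Win, Previous
Transition and Group (treatment-coded, control = 0); longitudinally the
full factorial including Time (baseline = 0). Bernoulli rows are
aggregated to binomial counts per subject-by-cell before fitting — an
identical likelihood, an order of magnitude faster.

The random-effects structure deserves its own paragraph, because the
field's most common choice — a random intercept per participant — turned
out to be wrong for calibrated group inference on this package's own
synthetic cohorts. When subjects genuinely differ in reward sensitivity
(they do, whenever `beta_mf` has between-subject spread), the intercept
absorbs only the subject's average stay tendency; the unmodelled
subject-level variation in the Previous Win effect deflates the standard
errors of all between-subject terms, and the null rejection rate of the
Group term climbs to roughly 9% at 200 trials instead of 5%. The default
is therefore a per-subject intercept *plus* Previous Win and Previous
Transition slopes (plus a Time slope in the longitudinal model), which
restores the Group term to roughly 6% — within sampling error of the
nominal rate once the normal-approximation (Wald) p-values are taken into
account. `random_slopes = FALSE` reproduces the intercept-only structure
for comparison with published analyses that use it.

Post-hoc group contrasts (`marginal_means_posthoc()`) are estimated
marginal means at previous win = -1 and +1, with the family of pairwise
group-by-reward contrasts adjusted by Tukey's method — the family is
exactly the grid printed in the output, no more. Group comparisons of
fitted parameters use two-sided Mann-Whitney tests (exact for small
tie-free samples), since fitted parameter distributions are generally
skewed; longitudinal parameter change uses 2 (Group) x 2 (Time)
mixed-design ANOVAs on subjects with both sessions. Relationships with
use-pattern covariates are Spearman correlations followed by ordinary
least-squares regressions of each (mean-centred) use variable on the five
parameters plus a days-since-last-use covariate, with variance-inflation
factors reported and per-variable outlier ranges applied as complete-case
exclusions. Beyond the Tukey family no multiplicity adjustment is applied,
matching common practice in this literature; interpret single uncorrected
p-values accordingly. Where Bayesian group tests are used in the
literature, this package deliberately provides the frequentist analogues
only.

## Numerical and design choices, in one place

* Walk parameters: reflecting bounds [0.25, 0.75], per-trial step SD
  0.025, uniform initial values — the standard convention for this task
  family; all configurable, and fixed walks can be loaded from CSV.
* Tutorial structure: 10 response-training, 20 second-stage-only, 20 full
  practice trials; practice data never enter analyses.
* Q initialization at 0; repetition indicator 0 on trial 1; likelihood
  floors at `1e-12`; transform clipping at `1e-9` with a warning.
* The chance-screen degrees of freedom are 5 per session, ignoring
  boundary effects.
* EM warm-starts subjects from their incumbent estimate after the first
  iteration (plus fresh jittered starts), which cuts runtime several-fold
  without changing the optimum in practice.
* Calibration replicates for the rank-sum and ANOVA tests run on the
  generating parameter tables of null cohorts: their calibration is a
  property of the tests given a parameter table, and refitting hundreds of
  cohorts by EM would add nothing but runtime.
* Problem sizes in the test suite: recovery uses 60 subjects with 5
  replicate datasets; calibration uses 500 null replicates at the default
  30/31 group sizes; the chance screen uses 100 simulated participants per
  condition.

## Known limitations

* The MB value rule is the common-state maximum; expectation-over-
  transitions variants and eligibility traces are out of scope (the rule
  is isolated in `mb_stage1_values()` to permit extension).
* Wald p-values from the mixed logistic regression are mildly
  anti-conservative at these cohort sizes even with random slopes
  (~1 percentage point at the 5% level).
* The Laplace approximation underlying the EM covariance update assumes a
  locally quadratic posterior; with very few valid trials per subject the
  prior dominates and between-subject shrinkage is strong.
* `beta_mb` is the hardest parameter to recover (its influence is masked
  whenever second-stage values are close or `beta_consistency` is low);
  expect its recovery correlation to be the weakest of the five.
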