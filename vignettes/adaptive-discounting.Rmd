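---
title: "Adaptive Bayesian measurement of delay discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Bayesian measurement of delay discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(adodisc)
library(dplyr)
```

## The measurement problem

Delay discounting — the devaluation of a reward with the delay to its
receipt — is one of the most widely used behavioural phenotypes in
psychiatry and decision science. The standard quantity of interest is the
hyperbolic discounting rate $k$ in

$$V = \frac{A}{1 + kD},$$

where an amount $A$ delivered after $D$ days is worth $V$ now. Choices
between a smaller-sooner option (value $V_{SS}$) and a larger-later option
(value $V_{LL}$) are linked to the model by a softmax (Luce) rule,

$$P(LL) = \frac{1}{1 + e^{\beta (V_{SS} - V_{LL})}},$$

with inverse temperature $\beta \ge 0$ governing choice consistency.
Inference targets $\log k$ (natural log), the scale on which individual
differences are approximately symmetric.

A fixed questionnaire spends most of its trials far from a participant's
indifference region, where choices carry almost no information about $k$.
This package implements the alternative: **adaptive design optimization
(ADO)**. Before every trial a grid posterior over $\theta = (\log k,
\beta)$ is updated with all previous choices, and the next stimulus $d$
(a sooner reward $r_{SS}$ at delay 0 versus \$800 at delay $t_{LL}$) is
the candidate maximizing the mutual information between parameters and
the upcoming binary outcome,

$$U(d) = \sum_{\theta} \sum_{y \in \{0,1\}} m(\theta)\, p(y \mid \theta, d)
  \log \frac{p(y \mid \theta, d)}{p(y \mid d)}
  = H\!\left[p(y \mid d)\right] - \mathbb{E}_{\theta}\,
    H\!\left[p(y \mid \theta, d)\right],$$

in nats. The comparator is the conventional adjusting-amount staircase:
starting from \$400 versus \$800 at each of seven delays (1 week to 10
years), the immediate amount moves by increments of 200, 100, 50, 25 and
12.5 dollars in the direction that makes the unchosen option more
attractive, bracketing one indifference point per delay in six choices
(42 trials in total, the same count as an adaptive session).

Because both methods produce the same kind of data — binary choices over
(reward, delay) pairs — both are fitted with the same grid posterior, so
method comparisons reflect the stimuli, not the estimator.

## What the package contains

* `ado_engine()`, `next_trial()`, `update_posterior()` — the sequential
  engine; `run_ado_session()` closes the loop against a simulated agent.
* `sc_start()`/`sc_next()`/`run_staircase()` — the staircase protocol,
  exact to the canonical worked trace, and `fit_dd_session()` /
  `cumulative_estimates()` for batch and prefix refits.
* `make_cohort()`, `respond()` — softmax-hyperbolic agents with optional
  lapses and between-visit drift of $\log k$.
* `ccc()`, `cumulative_trr()`, `trials_to_threshold()`,
  `fit_cohort_sessions()`, `exclude_outliers()`, `param_correlation()` —
  the evaluation metrics: reliability (Lin's concordance computed
  cumulatively per trial), precision (posterior SD of $\log k$),
  efficiency (trials to a reliability threshold).
* `run_visit()`, `run_two_visit_study()` — orchestration of
  multi-session, multi-visit simulated studies with counterbalanced task
  order.

## A single adaptive session

```{r session}
engine <- ado_engine()
agent <- make_cohort(1, seed = 8)
agent$true_log_k
session <- run_ado_session(agent, engine, n_trials = 42, seed = 1,
                           fit_engine = inference_grid())
tail(session, 3)
glance(attr(session, "fit"))
```

The engine converges on near-indifference stimuli within a handful of
trials; the posterior mean of $\log k$ lands within a few hundredths of
the generating value.

```{r sessionplot}
plot_session(session)
```

## Tunable parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `k_bounds` | `c(1e-5, 1)` | discounting-rate support (1/days); the upper bound of 1 accommodates steeply discounting clinical populations (an earlier bound of 0.1 is known to clip them) |
| `beta_bounds` | `c(0.2, 5)` | inverse temperature on dollar-scale value differences; 0.2 is near-random at the design granularity, 5 near-deterministic. The lower bound stays above 0 because $\beta = 0$ makes every design uninformative |
| `n_k`, `n_beta` | 150, 25 | selection-grid resolution (see below) |
| `r_ss` grid | \$12.5 … \$787.5 by \$12.5 | sooner-reward candidates; step equals the staircase's finest increment |
| `t_ll` grid | 1–3650 days (10 values) | later-delay candidates: the seven staircase delays plus 1, 3 and 90 days |
| lapse | 0 | probability of a uniformly random response |
| `drift_sd` | 0.1 | SD of the Normal perturbation of $\log k$ between visits |

Delays are stored in days; the verbal staircase delays map to
$\{7, 14, 30, 180, 365, 1095, 3650\}$ days (calendar-approximate
integers). Utilities are reported in nats; only their ordering matters
for selection. The prior is uniform over the grid. $\beta$ is gridded on
its natural scale (a log-scale grid is a config away via a custom
`prior`, but with bounds $[0.2, 5]$ the difference is immaterial).

## Numerical design: two grids, one model

Grid inference plays two roles with very different accuracy demands, and
the package deliberately separates them.

**Selection.** Scoring all 630 candidates each trial costs two
matrix–vector products against a precomputed likelihood cache. The
selection grid must stay fine enough that the posterior is not resolved
to a single cell mid-session: once that happens, every candidate has
expected information gain ≈ 0 and the argmax carries no signal. With
consistent responders (42 informative trials localize $\log k$ to a few
hundredths of a log-unit) a 50-point grid collapses; the default is 150
points. If the maximum utility still falls below $10^{-9}$ nats,
`next_trial()` presents the candidate whose predictive probability is
closest to 0.5 — near-indifference trials remain the locally most
informative choice for the remaining within-cell uncertainty. As a
further economy, grid cells whose relative posterior mass falls below
$10^{-15}$ are dropped from the utility scan (they cannot regain mass
under a product of Bernoulli likelihoods); this is exact to well below
reporting precision.

**Inference.** Reported estimates — trajectories of the posterior mean,
the posterior SD that defines the precision metric, and credible
intervals — are refits of the recorded choices on `inference_grid()`
(800 × 25 cells by default, no candidate cache). Adaptive stimulus
selection does not bias likelihood-based inference, so the refit is
exact. The credible interval treats the grid posterior as a
piecewise-constant density over cells and interpolates quantiles within
cells; with the discrete-atom reading a fully-resolved posterior would
yield zero-width intervals and badly under-cover. Interval calibration
additionally requires cells below roughly half the posterior SD — about
0.01 log-units for highly consistent responders after 42 adaptive
trials — so coverage checks use `inference_grid(n_k = 1600)`. In
calibration runs (200 consistent agents, 42 adaptive trials, three
cohort seeds) the 95% interval covered the generating $\log k$ 96–97%
of the time at 1600 cells, ~93% at 800, ~89% at 400, and only ~78% with
the 50-point discrete-atom reading — discretization, not the inference,
is what fails at coarse resolution. Per-trial estimate trajectories for
reliability curves use 200 cells: a concordance across participants
whose $\log k$ spans ~8.5 log-units is insensitive to quantization at
that scale.

Other numerical choices: softmax probabilities are computed with the
stable logistic and clamped to $[10^{-12}, 1 - 10^{-12}]$ so
log-likelihoods stay finite even when $\beta \cdot \Delta V$ reaches
hundreds; batch fits accumulate log-likelihood and normalize once;
sequential updates renormalize after every trial. Exact utility ties are
broken by the canonical candidate ordering (ascending later delay, then
ascending sooner reward), making sessions bit-reproducible.

## The synthetic cohort: what it does and does not emulate

`make_cohort()` draws $\log k \sim U[\log 10^{-4}, \log 0.5]$ — spanning
steep discounting of days-scale delays to shallow discounting of
years-scale delays, inside the engine's operative range — and
$\beta \sim \mathrm{LogNormal}(0, 0.5)$ (median 1). On dollar-scale
value differences a median-1 inverse temperature makes agents quite
consistent: only choices within roughly $\pm$\$10 of indifference are
effectively stochastic. Between-visit change is modelled as a single
Gaussian perturbation of $\log k$ (default SD 0.1); lapses default to 0.

Consequences worth keeping in mind when reading simulation results:

* Test-retest reliability of the adaptive method rises essentially
  immediately, because the first optimal stimulus already splits such a
  cohort reliably. Human curves rise over 5–15 trials; simulated
  consistent agents are an easier population than humans, so trials-to-
  threshold numbers here are lower bounds in flavour, and the
  interesting quantity is the *contrast* between methods under identical
  agents, which is preserved.
* Posterior SDs are an order of magnitude smaller than typical human
  values, again because simulated agents lack the inconsistency, fatigue
  and attention lapses of real participants (the lapse and drift knobs
  exist to reintroduce them).
* With $\log k$ and $\beta$ drawn independently and no lapses, the
  cohort correlation between recovered $\log k$ and $1/\beta$ is pure
  sampling noise. The adaptive method recovers $\beta$ well (its
  near-indifference trials identify it) and therefore reports that
  chance correlation faithfully, while staircase fits barely constrain
  $\beta$ and attenuate it — so this diagnostic, used on human data to
  reveal contamination of staircase estimates by response
  inconsistency, does not show an adaptive advantage on the default
  synthetic cohort. Reintroducing lapses is the knob that restores the
  contamination mechanism.
* No magnitude effects, no attention dynamics, no systematic response
  biases: the agents are the model. Passing tests demonstrate that the
  machinery measures the model's parameters correctly and efficiently —
  not that the hyperbolic/softmax model is true of people.

## Comparing the methods on a simulated cohort

The replication unit used by the test suite and the acceptance script is
a 100-agent cohort completing two adaptive and two staircase sessions
(42 trials each). Per-trial estimate trajectories use a 200-point
inference grid (reliability curves are insensitive to quantization at
that scale); final precision uses the 400-point grid. Cumulative
reliability is evaluated every trial for the adaptive method and every
third trial for the staircase, and the efficiency metric is the first
evaluated trial at which the curve reaches 0.9.

```{r cohort}
engine <- ado_engine()
fit_grid <- inference_grid(n_k = 200)
cohort <- make_cohort(30, seed = 501)
ado <- run_cohort_sessions(cohort, "ado", engine, n_sessions = 2,
                           seed = 701, fit_engine = fit_grid)
sc <- run_cohort_sessions(cohort, "sc", engine, n_sessions = 2,
                          seed = 701, estimate_at = seq(3, 42, 3),
                          fit_engine = fit_grid)
curve_ado <- cumulative_trr(estimate_trajectories(ado, 1),
                            estimate_trajectories(ado, 2))
curve_sc <- cumulative_trr(estimate_trajectories(sc, 1),
                           estimate_trajectories(sc, 2))
c(ado = trials_to_threshold(curve_ado), sc = trials_to_threshold(curve_sc))
autoplot(curve_sc)
```

```{r precision}
fits <- bind_rows(ado, sc) |>
  filter(session == 1) |>
  fit_cohort_sessions(grid = inference_grid())
fits |> group_by(method) |> summarise(precision = mean(sd_log_k))
```

Outlier screening follows the posterior-SD rule: participants whose
$\log k$ posterior SD exceeds the cohort mean by more than two cohort
SDs are excluded in a single pass (`exclude_outliers()`); the rule
defaults to the $\log k$ SD, with the column configurable.
`param_correlation()` reports the Pearson correlation between recovered
$\log k$ and $1/\beta$ — a diagnostic for contamination of the
discounting estimate by response inconsistency.

## Design choices that were genuinely open

* **One estimator for both methods.** Staircase choices are fitted with
  the same non-hierarchical grid posterior as the adaptive engine rather
  than a hierarchical sampler, so the comparison isolates stimulus
  selection. The staircase's classical readout — the per-delay
  indifference points — is computed and logged, but the headline
  staircase estimate is the fit to the raw 42 choices.
* **Indifference-point convention.** The staircase terminates after the
  choice at the amount produced by the final \$12.5 adjustment; that
  amount is the indifference point. This is the reading consistent with
  the canonical \$200/\$100/\$150 worked trace and six choices per
  delay.
* **Easy-trial policy.** Long runs of near-indifference trials are
  subjectively hard. The optional policy (off by default, and off in all
  reported simulations) inserts one easy trial — maximal
  $|p(y\!=\!1|d) - 0.5|$ — whenever the top-utility design has been
  stable for three consecutive selections, leaving the total trial count
  unchanged.
* **Confidence intervals for concordance.** Lin's coefficient uses
  population (1/n) moments; its 95% CI uses the Fisher-z transformation
  with Lin's asymptotic standard error. Reference implementations differ
  in moment conventions at small n, which is why the tests pin the
  convention against an independent in-test implementation.
* **Sessions are independent.** Within a visit each session restarts
  from the prior (no posterior carry-over), and within-visit session
  pairs share the agent's true parameters; drift applies only between
  visits. Counterbalancing of task order is recorded (`ado_first`), and
  because sessions share no state it cannot affect simulated results —
  it matters only for human use of the session schedule.

## Problem sizes

Simulation-backed checks in the test suite and the acceptance script
use: 200 agents × one 42-trial adaptive session for recovery and
interval calibration; 20 replications of the 100-agent two-method
replication unit for the directional method comparison; 50 seeds for
staircase recovery; 10,000 draws for distributional sanity checks. These
sizes give stable directions and percentages (binomial SE on a 95%
coverage estimate at n = 200 is ~1.5 points) at a few minutes of single-core
runtime per block.

## Known limitations

* Only the two-parameter hyperbolic/softmax model is implemented; no
  exponential or quasi-hyperbolic alternatives, and no model
  discrimination objective for the utility.
* The grid posterior is exact only up to discretization; parameters at
  the grid boundary (true $k$ at or above `k_bounds[2]`) produce
  clipped, boundary-piled posteriors — the bound exists to be widened in
  configuration, not to be trusted as a ceiling.
* The candidate set is fixed across trials; no pruning or continuous
  optimization of the design space.
* Agents are stationary within a session; fatigue or learning within a
  session is not modelled, so the easy-trial policy can only be
  exercised mechanically here, not validated behaviourally.
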