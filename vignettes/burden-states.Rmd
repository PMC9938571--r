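---
title: "Multimorbidity burden states, transitions, and healthy life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity burden states, transitions, and healthy life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morbstate` implements a complete analysis chain for studying how a binary
family-relationship exposure — weekly contact with children only
("downward") versus weekly contact with both children and grandparents
("two-way") — relates to multimorbidity in a wave-based panel survey of
middle-aged and older adults. The chain runs: synthetic cohort →
descriptives → weighted burden index and five ordered burden states →
Cox model of time to multimorbidity → progressive multi-state model →
multistate life tables. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design
choices, in that order. Real survey microdata are access-restricted, so
everything here runs on the package's synthetic cohorts; the last
section is explicit about what that does and does not demonstrate.

## The burden index and its discretization

Each participant reports doctor-diagnosed chronic conditions from a
fixed list (14 by default). A severity weight table maps each disease to
a positive, dimensionless weight, and the **multimorbidity burden
index** of a disease set is the sum of the weights of the diseases
present; the empty set has index 0. Weights are deliberately pure
configuration (`disease_weights()`, two-column CSV or YAML): the
published severity weights for the Chinese middle-aged and elderly
population are not redistributable, so the package ships a synthetic
table (`inst/extdata/disease_weights_synthetic.csv`) whose values are
calibration choices, not literature estimates. **Multimorbidity** itself
is defined by count, not weight: two or more concurrent conditions.

`enumerate_clusters()` lists all $2^d$ disease subsets ("clusters") with
their index values, in a deterministic bit-order, refusing $d > 20$.
`kmeans_1d()` then divides the index line into $k = 5$ ordered levels
S1–S5 (higher = more severe), with death as the sixth, absorbing state.
Because one-dimensional least-squares clusters are contiguous on the
sorted values, the partition is found *exactly* by dynamic programming
over split points (divide-and-conquer over the monotone argmin), not by
seeded Lloyd iterations: the optimum is deterministic and reproducible,
which matters because every downstream stage depends on the state
labels. Level boundaries are midpoints between adjacent-cluster
extremes; interval assignment is half-open with a value on a boundary
going to the **higher** (more severe) state — an arbitrary but fixed
tie-break.

Two fitting populations are supported. Clustering the attainable
cluster index values from the exhaustive enumeration weights every
subset equally, which centres the boundaries in the middle of the
subset-sum distribution; on realistic cohorts, where most person-waves
carry zero to three conditions, nearly everyone then lands in S1 and
the transition model degenerates. The pipeline therefore defaults to
clustering the **observed person-wave index values**
(`cluster_on = "observed"`), so the five levels describe the burden the
cohort actually carries; `cluster_on = "clusters"` remains available.

## Time to multimorbidity and the Cox model

The onset analysis dates the "second diagnosis" by the first wave at
which a participant reports two or more conditions, measuring time from
baseline; participants multimorbid at baseline are excluded
(incident-case analysis), participants who never reach two conditions
are censored at their last observation alive, and deaths before
multimorbidity are censored at the exact death time. Event times sit on
wave offsets by construction — no midpoint imputation — because the
survey only dates diagnoses by report wave. The wave design makes ties
heavy, so `fit_cox()` maximises the **Efron**-corrected log partial
likelihood by damped Newton iterations (Breslow by flag), declaring
convergence at a score max-norm below $10^{-8}$ (or a Newton step at
machine precision) and reporting monotone likelihood as a diagnosed
non-convergence. Kaplan–Meier curves (`kaplan_meier()`) use Greenwood
variance with log–log 95% bands.

`schoenfeld_test()` checks proportionality with scaled Schoenfeld
residuals: a Grambsch–Therneau score test of zero slope against a
transform of event time, per covariate (1 df) and globally. The default
transform is the **event-time rank** (identity time by flag), and the
variance uses the average-information approximation
$\bar V = \mathcal I(\hat\beta)/d$; `survival::cox.zph` (survival ≥ 3)
recomputes per-event variances, so the two statistics agree closely but
not exactly. The package's own test is calibrated: under exact
proportional hazards its rejection rate at $\alpha = 0.05$ stays within
binomial error across 200 simulated replicates (see the acceptance
suite).

## The progressive multi-state model

Burden is assumed to stay constant or worsen, never to reverse, because
disease histories are retrospective ("ever diagnosed"): the state space
allows every forward transition $r \to s$, $r < s$, among living states
plus $r \to$ death, optionally restricted by a mask (e.g.
`adjacent_transitions()`). Transition intensities are log-linear in
covariates, msm-style:
$$q_{rs}(z) = q^{(0)}_{rs} \exp(\beta_{rs}^\top z),$$
so $\exp(\beta_{rs})$ is a per-transition hazard ratio; the reference
level of the group covariate is the downward relationship. Covariates
are centred before entering the linear predictor (age at 60 by
default), so baseline intensities refer to a 60-year-old in the
reference group.

Living states are interval-censored at waves; deaths carry exact dates.
A participant contributes the product over consecutive observation
pairs of $P_{s_i s_{i+1}}(\Delta t_i; z)$ with $P(t) = e^{Qt}$, and a
death at time $T$ after a last living observation in state $r$
contributes $\sum_{s\ \mathrm{living}} P_{rs}(T - t_{\mathrm{last}};
z)\, q_{s,\mathrm{death}}(z)$ — the state on the eve of death is
unobserved and marginalised. Age is updated annually within intervals
(piecewise-constant intensities), so a two-year interval is a product
of two one-year matrices; this requires integer baseline ages and wave
gaps, which the survey design provides. `panel_log_likelihood()` is
checked against brute-force latent-state enumeration to $10^{-10}$.

Numerics: the public `transition_probability()` uses the
scaling-and-squaring matrix exponential (`Matrix::expm`), and the
likelihood hot path uses an equivalent **uniformization** series
$P(t) = \sum_k \mathrm{Pois}(k; \Lambda t)\, (I + Q/\Lambda)^k$ in
compiled code, truncated when the Poisson tail is far below $10^{-12}$
and with the residual tail folded into the last term; the two agree to
machine precision and uniformization is robust for the
upper-triangular generators of progressive models. Death terms reuse
the same series as a matrix–vector action, grouped by covariate
pattern and age-year so all fractional death times are handled in one
vectorised call.

`fit_multistate()` maximises the panel likelihood by BFGS on
$(\log q^{(0)}, \beta)$, with a forward-difference gradient, a staged
start (baseline rates first, then covariate effects), and a smooth
penalty wall for per-year rates outside $[e^{-30}, 20]$ — panel data
observed at multi-year gaps cannot identify faster rates, and the wall
keeps the series truncation bounded during line searches. Standard
errors come from the inverse finite-difference observed information
(step $10^{-5}$ on the working scale). Candidate transitions with no
observed pair that could contain them are dropped with a warning before
fitting. The pipeline default puts the group effect on every retained
transition and the age effect on the transitions into death only,
where ageing acts most strongly; this halves the parameter count of
the default fit, and both restrictions are plain configuration
(`covariate_transitions`).

Recovery behaviour at the study's scale is part of the test suite:
simulating cohorts of $n = 3{,}000$ at a true transition hazard ratio
of 0.83 (the protective effect size the analysis is powered around),
the Wald 95% intervals cover the truth in ≥ 85% of 100 seeded
replicates and the mean estimated HR is within 10% of the truth.

## Multistate life tables

`age_specific_probabilities()` evaluates the fitted generator at each
integer age $x$ (other covariates fixed at a chosen profile) and
returns one-year matrices $P_x$. `build_life_table()` advances a radix
cohort (default 100,000, all in S1 at age 45) through the $P_x$,
absorbing the death column into a cumulative-deaths track; state
person-years use the linear within-interval convention
$L(x,s) = (l(x,s) + l(x+1,s))/2$, and at the closure age
$\omega = 110$ survivors contribute $a_\omega = 0.5$ further years in
their current state. Then
$$\mathrm{LE}(x) = \frac{\sum_{y \ge x}\sum_{s} L(y,s)}{\sum_s l(x,s)},
\qquad
\mathrm{HLE}(x) = \frac{\sum_{y \ge x}\sum_{s \in H} L(y,s)}{\sum_s l(x,s)},$$
and years of healthy life lost to multimorbidity is
$\mathrm{LE} - \mathrm{HLE} \ge 0$. Which burden levels count as
"healthy" is genuinely open — the source analyses never defined the
set — so $H$ is explicit configuration defaulting to $\{S1\}$ (the
essentially disease-free level under observed-value clustering), and
the workflow reports the $\{S1, S2\}$ alternative as sensitivity. All
conventions ($\omega$, $a_\omega$, radix, starting distribution) are
arguments. The table arithmetic is validated three ways: closed forms
(certain death gives LE = 0.5; no mortality gives $\omega - x + 0.5$;
constant hazard $\mu$ gives LE $\approx 1/\mu$), exact identities
(conservation of the radix, HLE ≤ LE, radix invariance to $10^{-9}$,
state-wise decomposition of years lost), and a 100,000-path cohort
microsimulation using the same matrices and person-year convention,
which must agree within three Monte-Carlo standard errors.

No interval estimates are attached to LE/HLE: the replicate spread
under reseeding is the package's uncertainty summary, and bootstrap
intervals are out of scope.

## The synthetic cohorts

`simulate_cohort()` has two modes, both seeded and split into
per-participant substreams so individual draws are reproducible under
reordering.

**State mode** simulates trajectories directly from a known
`intensity_model()` by competing exponential clocks (next-jump time
exponential at the total outflow; destination categorical in the
intensities), with age-dependent intensities frozen within one-year
steps, then observes them at waves. It exists for parameter recovery:
the generating intensities are returned as ground truth.

**Disease mode** draws baseline prevalent conditions (default 6% per
disease), exponential onset clocks per remaining disease with
log-linear age effects (+2%/year, centred at 60) and a group hazard
ratio of 0.83 on onsets in the two-way group, and a mortality hazard
increasing in age (+9%/year) and current condition count (+20% per
condition, roughly, via coefficient 0.18), sampled piecewise-exponentially
between onset and year breakpoints. The defaults are the study
conditions the analysis assumes: about 6,800 participants aged 45–90
(discretised exponential age distribution, ~95% at or below 65, the
two-way group slightly younger), a 60/40 two-way/downward split, waves
at 0/2/4/7 years, baseline multimorbidity near 18% and roughly 40%
incident multimorbidity over follow-up — chosen once to sit in the
range reported for ageing-cohort surveys of this design, and not
revisited. What the generator does **not** emulate: real-world marginal
prevalences of specific named diseases, correlated disease clusters
(onsets are conditionally independent), informative dropout (everyone
is observed until death or the last wave), recall error, or survey
weights. Passing tests therefore demonstrate that the estimators
recover the truth under the stated model, not that the published
real-data estimates are reproducible — those require the restricted
survey microdata.

Participants with prevalent conditions at baseline enter the
multi-state stage in whatever state their baseline index implies; the
alternative, excluding them (`exclude_prevalent_msm = TRUE`), is kept
because the source description does not say how prevalent cases were
handled. The Cox stage always excludes baseline-multimorbid
participants.

## Descriptive statistics

`chi_square_test()` wraps the Pearson chi-square with Yates continuity
correction for 2×2 tables and the plain statistic otherwise. That
convention was chosen because it reproduces all seven published
two-group baseline statistics from the printed counts to three
decimals (the uncorrected 2×2 statistics do not), and those counts
ship as an exact fixture (`table1_counts()`). The inclusion-criteria
flow (responded to more than two surveys; age ≥ 45; a living parent or
parent-in-law; a living child; weekly contact with children; then
outcome-abnormal and covariate-missing exclusions) is applied in order
with a per-step attrition log; `attrition_fixture()` reconstructs a
respondent-flag table that reproduces the published flow
25,586 → 6,799 → 6,776 → 6,768 and is synthetic in every other
respect.

## Problem sizes and runtime choices

The test suite exercises the estimators at: $n = 3{,}000$ × 100
replicates for multi-state recovery; 200 replicates of $n = 150$ for
Schoenfeld calibration; 100,000 microsimulation paths for the life
table; a 500-participant end-to-end pipeline run twice to confirm
byte-identical outputs; and exhaustive oracles at $n \le 12$ for the
clustering DP and $n \le 8$ for the Cox grid search. The analysis
scripts run the full 6,800-participant cohort. These sizes were chosen
so each check has the power its tolerance needs on a single CPU.

## Known limitations

* The multi-state model is time-homogeneous apart from the annually
  updated age covariate; cohort/period effects and time-varying
  covariates beyond age are not modelled.
* State misclassification (hidden-Markov extensions) and reversible
  transitions are out of scope by design — the progressive assumption
  follows from retrospective disease ascertainment.
* Life-table extrapolation beyond the observed age range rests on the
  log-linear age effect; estimates at high ages inherit that
  parametric assumption.
* The per-covariate Schoenfeld statistic uses the average-information
  approximation, so it is a close cousin, not a twin, of
  `survival::cox.zph`.
* LE/HLE carry no analytic confidence intervals; use reseeded
  replicates for spread.
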