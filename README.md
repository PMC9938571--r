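# morbstate

Multimorbidity burden states, transitions, and healthy life expectancy in
wave-based panel cohorts.

## The problem

In ageing multi-generation families, the middle ("second") generation may
keep weekly contact only with their children (a *downward*
multi-generational relationship) or with both children and grandparents
(*two-way*). `morbstate` implements the full analysis chain for asking how
that exposure relates to chronic-disease accumulation in a CHARLS-style
panel survey (baseline plus follow-ups at 2, 4 and 7 years, interval-
censored disease reports, exactly dated deaths):

1. **Multimorbidity onset** — time from baseline to the first wave
   reporting two or more chronic conditions, analysed with Kaplan–Meier
   curves and a Cox proportional-hazards model
   $\lambda(t \mid z) = \lambda_0(t)\exp(\beta^\top z)$ (Efron ties,
   Schoenfeld-residual diagnostics).
2. **Burden-state progression** — a weighted multimorbidity burden index
   $B = \sum_{d \in \text{present}} w_d$, discretized into five ordered
   states S1–S5 by *exact* one-dimensional k-means (dynamic programming,
   no seeds), plus death as absorbing S6; a progressive continuous-time
   Markov multi-state model with log-linear intensities
   $q_{rs}(z) = q^{(0)}_{rs} e^{\beta_{rs}^\top z}$ fitted to the
   interval-censored panel by maximum likelihood, $P(t) = e^{Qt}$.
3. **Healthy life expectancy** — multistate life tables built from the
   fitted one-year transition matrices per age, yielding LE, HLE
   (expected years in the designated healthy states) and years of healthy
   life lost, LE − HLE, per relationship group.

Real survey microdata are access-restricted, so the package ships a
seeded synthetic cohort generator with the same design (two modes:
disease-level indicators for the full pipeline, and state-level
trajectories from known intensities for parameter recovery). The
published baseline contingency table is included as an exact fixture and
its chi-square statistics are reproduced to the printed precision.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
6,800-participant synthetic cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_descriptives.R
Rscript analysis/03_burden_states.R
Rscript analysis/04_cox.R
Rscript analysis/05_multistate.R
Rscript analysis/06_life_table.R
```

`04_cox.R` prints, for the default seed:

```
risk set: 5449 incident-risk participants (1351 excluded as multimorbid at baseline), 2173 events
  multimorbidity-free probability at year 7, group downward: 0.543 (0.522-0.565)
  multimorbidity-free probability at year 7, group two-way: 0.622 (0.605-0.639)
adjusted HR for two-way vs downward: 0.830 (95% CI 0.761-0.904, p = 2.11e-05)
proportional-hazards global test: X2 = 8.58 on 12 df, p = 0.738
```

Participants already multimorbid at baseline are excluded from the risk
set; the hazard ratio below 1 reflects the protective onset effect the
generator plants in the two-way group (true per-disease onset HR 0.83),
and the Schoenfeld global test is consistent with proportional hazards,
as it should be for data generated under them. `05_multistate.R` refits
the known-truth cohort:

```
recovery check: true S1->S2 group HR 0.830, estimated 0.821 (95% CI 0.748-0.900)
```

and `06_life_table.R` converts the fitted transition model into
per-group life tables:

```
downward  LE(45) = 34.82  HLE(45) =  6.15  years lost = 28.68
twoway    LE(45) = 36.79  HLE(45) =  7.57  years lost = 29.21
```

LE(45) is remaining life expectancy at age 45; HLE counts only years
expected in S1 (the lowest burden level, essentially disease-free under
the default discretization), so most remaining years are lived with some
burden — the gap is the years of healthy life lost to multimorbidity.
These are properties of the synthetic cohort, not estimates for any real
population.

In code, the same pipeline is one call:

```r
library(morbstate)
cfg <- pipeline_config(out_dir = "results/run1", seed = 1,
                       n_participants = 500)
bundle <- run_pipeline(cfg)
bundle$report
```

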