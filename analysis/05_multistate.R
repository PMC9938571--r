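#!/usr/bin/env Rscript
# Progressive Markov multi-state model on the five burden states plus
# death: interval-censored panel likelihood with exact death times,
# relationship-group effects on every retained transition and an age
# effect on the transitions into death. Also refits the state-mode
# recovery cohort against its known generating parameters.

library(morbstate)

panel <- read_panel("results/state_panel.csv")
ss <- state_space(5L)
fit <- suppressWarnings(
  fit_multistate(panel, ss, covariate_names = c("group", "age"),
                 covariate_transitions = list(age = "death")))
message(sprintf("multi-state fit: logLik %.1f, %s",
                fit$loglik,
                if (fit$converged) "converged" else "NOT converged"))
hr <- transition_hazard_ratio_table(fit, "group")
write.csv(hr, "results/transition_hr.csv", row.names = FALSE)
message("group hazard ratios by transition (two-way vs downward):")
for (i in seq_len(nrow(hr)))
  message(sprintf("  %-12s HR = %6.3f (%.3f-%.3f)", hr$transition[i],
                  hr$hr[i], hr$lower[i], hr$upper[i]))
yaml::write_yaml(list(
  loglik = fit$loglik, converged = fit$converged,
  transitions = morbstate:::transition_names(fit$state_space),
  theta = as.list(fit$theta), se = as.list(fit$se)),
  "results/msm_fit.yaml")

# parameter recovery on the cohort with known intensities
rp <- read_panel("results/cohort/recovery_panel.csv")
ssr <- state_space(3L, transitions = cbind(c(1L, 2L, 1L, 2L, 3L),
                                           c(2L, 3L, 4L, 4L, 4L)))
rfit <- fit_multistate(rp, ssr, covariate_names = "group",
                       covariate_transitions = list(group = 1L),
                       age_update = FALSE)
i <- length(rfit$theta)
message(sprintf("recovery check: true S1->S2 group HR 0.830, estimated %.3f (95%% CI %.3f-%.3f)",
                exp(rfit$theta[i]), exp(rfit$theta[i] - 1.96 * rfit$se[i]),
                exp(rfit$theta[i] + 1.96 * rfit$se[i])))
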