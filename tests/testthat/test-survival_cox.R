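test_that("time to multimorbidity follows the second-diagnosis rule", {
  panel <- data.frame(
    id = rep(1:4, each = 4),
    years_since_baseline = rep(c(0, 2, 4, 7), 4),
    vital_status = "alive",
    n_conditions = c(1, 2, 2, 3,   # event at wave offset 2
                     2, 2, 3, 3,   # multimorbid at baseline: excluded
                     0, 0, 0, 0,   # censored at 7
                     1, 1, 1, 1),  # censored at 7
    group = rep(c(0, 1, 0, 1), each = 4))
  tt <- derive_time_to_multimorbidity(panel, "group")
  expect_equal(tt$excluded_baseline_multimorbid, 2)
  r <- tt$records
  expect_equal(r$time[r$id == 1], 2)
  expect_equal(r$event[r$id == 1], 1L)
  expect_equal(r$time[r$id == 3], 7)
  expect_equal(r$event[r$id == 3], 0L)
  # death before multimorbidity censors at the exact death time
  pd <- data.frame(id = 9, years_since_baseline = c(0, 2, 3.4),
                   vital_status = c("alive", "alive", "dead"),
                   n_conditions = c(0, 1, 1))
  rd <- derive_time_to_multimorbidity(pd)$records
  expect_equal(rd$time, 3.4)
  expect_equal(rd$event, 0L)
})

test_that("Kaplan-Meier matches the hand product-limit calculation", {
  r <- data.frame(time = c(1, 2, 3), event = c(1L, 0L, 1L))
  km <- kaplan_meier(r)
  expect_equal(km$estimate, c(2 / 3, 2 / 3, 0))
  # all censored: constant 1
  kc <- kaplan_meier(data.frame(time = c(1, 2, 5), event = 0L))
  expect_true(all(kc$estimate == 1))
  expect_error(kaplan_meier(data.frame(time = numeric(0), event = integer(0))),
               "empty")
  # non-increasing step function on arbitrary data
  set.seed(4)
  rr <- data.frame(time = stats::rexp(60), event = stats::rbinom(60, 1, 0.6))
  expect_true(all(diff(kaplan_meier(rr)$estimate) <= 1e-12))
})

test_that("Kaplan-Meier agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(5)
  rr <- data.frame(time = ceiling(stats::rexp(150, 0.2)),
                   event = stats::rbinom(150, 1, 0.7))
  km <- kaplan_meier(rr)
  sf <- survival::survfit(survival::Surv(rr$time, rr$event) ~ 1,
                          conf.type = "log-log")
  i <- match(sf$time, km$time)
  expect_equal(km$estimate[i], sf$surv, tolerance = 1e-12)
  ok <- !is.na(sf$lower)   # survfit leaves bounds NA once S hits 0
  expect_equal(km$lower[i][ok], sf$lower[ok], tolerance = 1e-10)
  expect_equal(km$upper[i][ok], sf$upper[ok], tolerance = 1e-10)
})

test_that("label-symmetric data give a null Cox coefficient", {
  base <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                     event = c(1L, 1L, 0L, 1L, 1L, 0L))
  rec <- rbind(cbind(base, x = 0), cbind(base, x = 1))
  fit <- fit_cox(rec, "x")
  expect_lt(abs(fit$coefficients[["x"]]), 1e-7)
  expect_equal(unname(fit$hr[1L]), 1, tolerance = 1e-6)
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  rec <- data.frame(time = c(1, 2, 3, 4.5, 5, 7),
                    event = c(1L, 1L, 1L, 0L, 1L, 1L),
                    x = c(1, 0, 1, 1, 0, 0))
  fit <- fit_cox(rec, "x")
  pl <- function(b) morbstate:::.cox_ll(b, rec$time, rec$event,
                                        cbind(x = rec$x), "efron")$ll
  grid <- seq(-4, 4, by = 1e-4)
  vals <- vapply(grid, pl, numeric(1))
  b_grid <- grid[which.max(vals)]
  expect_lt(abs(fit$coefficients[["x"]] - b_grid), 1e-3)  # grid resolution
  # refine by golden-section-free local grid around the optimum
  grid2 <- seq(b_grid - 2e-4, b_grid + 2e-4, by = 1e-7)
  b_fine <- grid2[which.max(vapply(grid2, pl, numeric(1)))]
  expect_lt(abs(fit$coefficients[["x"]] - b_fine), 1e-6)
  # score vanishes at the reported optimum
  expect_lt(fit$score_norm, 1e-8)
})

test_that("Cox fit agrees with coxph under heavy ties, both tie methods", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 300
  x1 <- stats::rbinom(n, 1, 0.5); x2 <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.1 * exp(0.7 * x1 - 0.3 * x2))
  time <- ceiling(pmin(tt, 8))
  ev <- as.integer(tt <= 8)
  rec <- data.frame(time = time, event = ev, x1 = x1, x2 = x2)
  for (tie in c("efron", "breslow")) {
    fit <- fit_cox(rec, c("x1", "x2"), ties = tie)
    ref <- survival::coxph(survival::Surv(time, ev) ~ x1 + x2, ties = tie)
    expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(fit$loglik, ref$loglik[2L], tolerance = 1e-9)
  }
})

test_that("Wald intervals cover a true hazard ratio of 2", {
  set.seed(29)
  cover <- 0
  nrep <- 40
  for (r in seq_len(nrep)) {
    n <- 400
    x <- stats::rbinom(n, 1, 0.5)
    tt <- stats::rexp(n, 0.15 * exp(log(2) * x))
    cens <- stats::runif(n, 2, 10)
    rec <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens), x = x)
    fit <- fit_cox(rec, "x")
    if (fit$hr_lower[1L] <= 2 && 2 <= fit$hr_upper[1L]) cover <- cover + 1
  }
  # nominal 95%: allow binomial slack at 40 replicates
  expect_gte(cover, 33)
})

test_that("Schoenfeld machinery satisfies its identities and guards", {
  set.seed(6)
  n <- 200
  x <- stats::rbinom(n, 1, 0.5)
  z <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.2 * exp(0.4 * x))
  rec <- data.frame(time = tt, event = 1L, x = x, z = z)
  fit <- fit_cox(rec, c("x", "z"))
  ph <- schoenfeld_test(fit)
  # residuals at event times sum to zero at the MLE (score identity)
  expect_lt(max(abs(colSums(ph$residuals))), 1e-6)
  expect_equal(nrow(ph$table), 2L)
  expect_true(all(ph$table$p >= 0 & ph$table$p <= 1))
  # residuals match the survival package's Schoenfeld residuals
  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(tt, rep(1L, n)) ~ x + z, ties = "efron")
  rr <- stats::residuals(ref, type = "schoenfeld")
  expect_equal(unname(ph$residuals[, 1L]), unname(rr[, 1L]), tolerance = 1e-4)

  one <- data.frame(time = c(1, 2), event = c(1L, 0L), x = c(0, 1))
  f1 <- suppressWarnings(fit_cox(one, "x"))
  expect_error(schoenfeld_test(f1), "nsufficient events|fewer events")
})

test_that("a strong proportional-hazards violation is detected", {
  set.seed(30)
  n <- 600
  x <- stats::rbinom(n, 1, 0.5)
  # crossing hazards: effect reverses over time
  t1 <- stats::rexp(n, 0.5 * exp(1.5 * x))
  t2 <- 1 + stats::rexp(n, 0.5 * exp(-1.5 * x))
  tt <- ifelse(t1 < 1, t1, t2)
  rec <- data.frame(time = tt, event = 1L, x = x)
  fit <- fit_cox(rec, "x")
  ph <- schoenfeld_test(fit)
  expect_lt(ph$table$p[1L], 0.01)
})
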