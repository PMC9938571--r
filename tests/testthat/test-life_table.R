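test_that("age-specific matrices respond to the age effect as expected", {
  ss <- ss_chain_death()
  b <- matrix(NA_real_, 5, 1)
  b[3:5, 1] <- 0.09   # age acts on the three death transitions
  m <- intensity_model(ss, c(0.1, 0.08, 0.01, 0.02, 0.04), b,
                       covariates = "age", centers = c(age = 60))
  pm <- age_specific_probabilities(m, 45:80)
  expect_length(pm, 36L)
  for (P in pm) expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  death_at <- vapply(pm, function(P) P[1, 4], numeric(1))
  expect_true(all(diff(death_at) > 0))
  # no age effect: all matrices identical
  m0 <- intensity_model(ss, c(0.1, 0.08, 0.01, 0.02, 0.04))
  pm0 <- age_specific_probabilities(m0, 45:50)
  for (P in pm0) expect_equal(P, pm0[[1L]])
  expect_error(age_specific_probabilities(m, 40:50), "45")
})

test_that("life-table closure arithmetic matches the trivial cases", {
  ns <- 3L
  # certain death within the first year: LE = half-interval credit
  Pdead <- matrix(0, ns, ns); Pdead[, ns] <- 1; Pdead[ns, ns] <- 1
  lt <- build_life_table(rep(list(Pdead), 10), start_age = 45)
  expect_equal(life_expectancy(lt, 45), 0.5)
  # no mortality until closure: LE = omega - x + a_omega
  lt2 <- build_life_table(rep(list(diag(ns)), 20), start_age = 45)
  expect_equal(life_expectancy(lt2, 45), 20.5)
  expect_equal(life_expectancy(lt2, 50), 15.5)
  expect_error(build_life_table(list(matrix(0.3, 3, 3))), "stochastic")
})

test_that("constant-hazard life expectancy approaches 1/mu", {
  mu <- 0.08
  m <- intensity_model(ss_alive_dead(), mu)
  P1 <- transition_probability(build_intensity_matrix(m), 1)
  lt <- build_life_table(rep(list(P1), 400), start_age = 45)
  expect_lt(abs(life_expectancy(lt, 45) - 1 / mu), 0.5)
})

test_that("life-table identities: conservation, HLE <= LE, radix invariance", {
  ss <- ss_chain_death()
  b <- matrix(0, 5, 1); b[3:5, 1] <- 0.09
  m <- intensity_model(ss, c(0.12, 0.1, 0.01, 0.03, 0.05), b,
                       covariates = "age", centers = c(age = 60))
  pm <- age_specific_probabilities(m, 45:109)
  lt <- build_life_table(pm, radix = 1e5, start_age = 45)
  # deaths absorb everything the living occupancy loses
  expect_lt(max(abs(rowSums(lt$l) + lt$deaths - 1e5)), 1e-6)
  le <- life_expectancy(lt, 45)
  for (hs in list("S1", c("S1", "S2"), c("S1", "S2", "S3"))) {
    expect_lte(healthy_life_expectancy(lt, 45, hs), le + 1e-12)
  }
  expect_equal(healthy_life_expectancy(lt, 45, c("S1", "S2", "S3")), le)
  expect_error(healthy_life_expectancy(lt, 45, character(0)), "non-empty")
  expect_error(healthy_life_expectancy(lt, 45, "S9"), "not living")
  # years lost decomposes as LE - HLE and is the unhealthy sojourn
  yl <- years_lost(lt, 45, "S1")
  expect_equal(yl, le - healthy_life_expectancy(lt, 45, "S1"))
  unhealthy <- healthy_life_expectancy(lt, 45, c("S2", "S3"))
  expect_equal(yl, unhealthy, tolerance = 1e-9)
  # radix invariance
  lt1 <- build_life_table(pm, radix = 1, start_age = 45)
  expect_equal(life_expectancy(lt1, 45), le, tolerance = 1e-9)
  expect_equal(healthy_life_expectancy(lt1, 45, "S1"),
               healthy_life_expectancy(lt, 45, "S1"), tolerance = 1e-9)
  # LE strictly decreasing in age under positive mortality
  summ <- life_expectancy_summary(lt, healthy_states = "S1")
  expect_true(all(diff(summ$LE) < 0))
})

test_that("life-table occupancy matches a cohort microsimulation", {
  ss <- ss_chain_death()
  b <- matrix(0, 5, 1); b[3:5, 1] <- 0.09
  m <- intensity_model(ss, c(0.12, 0.1, 0.01, 0.03, 0.05), b,
                       covariates = "age", centers = c(age = 60))
  pm <- age_specific_probabilities(m, 45:109)
  lt <- build_life_table(pm, radix = 1e5, start_age = 45)
  nsim <- 20000
  sim <- microsim_years(pm, nsim, healthy = 1L, seed = 99)
  le_se <- stats::sd(sim$total) / sqrt(nsim)
  hle_se <- stats::sd(sim$healthy) / sqrt(nsim)
  expect_lt(abs(life_expectancy(lt, 45) - mean(sim$total)), 3 * le_se)
  expect_lt(abs(healthy_life_expectancy(lt, 45, "S1") - mean(sim$healthy)),
            3 * hle_se)
})
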