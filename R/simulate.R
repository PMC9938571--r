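#' Simulation configuration for synthetic panel cohorts
#'
#' Two generator modes share the survey design of a four-wave longitudinal
#' study of Chinese adults aged 45+ (baseline plus follow-ups 2, 4 and 7
#' years later), with a binary family multi-generational relationship
#' exposure (downward = weekly contact with children only, the reference;
#' two-way = weekly contact with children and grandparents, drawn with
#' probability `group_probability`, default 0.60 to mirror the roughly
#' 40/60 split of such cohorts):
#'
#' * `mode = "state"` simulates burden-state trajectories directly from a
#'   known progressive [intensity_model()] — used for parameter recovery,
#'   since the generating intensities are returned as ground truth.
#' * `mode = "disease"` simulates per-disease chronic-condition onsets
#'   (exponential onset clocks, log-linear covariate and group effects)
#'   plus state/age-dependent mortality — used to exercise the burden
#'   index, clustering, Cox and descriptive stages end to end.
#'
#' Living states are observed only at waves (interval censoring); deaths
#' carry exact dates, mirroring survey exit interviews.
#'
#' @param n_participants cohort size.
#' @param seed integer seed; the cohort is deterministic given the seed and
#'   per-participant substreams make individual draws independent of
#'   participant order.
#' @param mode `"state"` or `"disease"`.
#' @param wave_offsets_years strictly increasing, starting at 0.
#' @param group_probability probability of the two-way relationship group.
#' @param age_range inclusive integer baseline age bounds.
#' @param age_decay rate of the (truncated, discretised) exponential
#'   baseline-age distribution per group, named `downward` / `twoway`;
#'   larger = younger. Defaults give ~92-96% aged 65 or below.
#' @param covariate_spec named list of marginal specs for extra baseline
#'   covariates; each is `list(type = "binary", p = ...)` or
#'   `list(type = "categorical", levels = ..., probs = ...)` or
#'   `list(type = "lognormal", meanlog = ..., sdlog = ...)`.
#' @param true_intensities (state mode) an [intensity_model()]; its
#'   covariates may include `group` and `age` (updated annually).
#' @param disease_onset_hazards (disease mode) named positive per-year
#'   onset hazards, one per disease.
#' @param baseline_prevalence (disease mode) named per-disease probability
#'   of already having the disease at baseline (recycled if scalar).
#' @param group_onset_hr (disease mode) hazard ratio multiplying every
#'   onset hazard in the two-way group; default 0.83, the protective
#'   effect size used throughout the package's simulation studies.
#' @param onset_age_coef (disease mode) log-hazard slope per year of age
#'   (centred at 60) on onset hazards.
#' @param mortality (disease mode) list with `base` (annual hazard at age
#'   60 with no conditions), `age_coef` (log-hazard per year of age) and
#'   `count_coef` (log-hazard per current condition); mortality increases
#'   with both.
#' @param horizon_years follow-up horizon (default last wave offset).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants,
                              seed = 1L,
                              mode = c("disease", "state"),
                              wave_offsets_years = c(0, 2, 4, 7),
                              group_probability = 0.60,
                              age_range = c(45L, 90L),
                              age_decay = c(downward = 0.13, twoway = 0.18),
                              covariate_spec = default_covariate_spec(),
                              true_intensities = NULL,
                              disease_onset_hazards = NULL,
                              baseline_prevalence = 0.06,
                              group_onset_hr = 0.83,
                              onset_age_coef = 0.02,
                              mortality = list(base = 0.008, age_coef = 0.09,
                                               count_coef = 0.18),
                              horizon_years = NULL) {
  mode <- match.arg(mode)
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1L)
  wave_offsets_years <- as.numeric(wave_offsets_years)
  if (wave_offsets_years[1L] != 0 || any(diff(wave_offsets_years) <= 0))
    stop("wave offsets must be strictly increasing and start at 0")
  if (!(group_probability > 0 && group_probability < 1))
    stop("group_probability must be in (0, 1)")
  if (mode == "state") {
    if (is.null(true_intensities) || !inherits(true_intensities, "intensity_model"))
      stop("state mode needs true_intensities (an intensity_model)")
  } else {
    if (is.null(disease_onset_hazards))
      disease_onset_hazards <- default_onset_hazards()
    if (is.null(names(disease_onset_hazards)))
      stop("disease_onset_hazards must be named by disease")
    if (any(disease_onset_hazards < 0)) stop("onset hazards must be >= 0")
    baseline_prevalence <- rep_len(baseline_prevalence,
                                   length(disease_onset_hazards))
    names(baseline_prevalence) <- names(disease_onset_hazards)
    if (any(mortality$base <= 0)) stop("mortality base hazard must be > 0")
  }
  if (is.null(horizon_years)) horizon_years <- max(wave_offsets_years)
  structure(list(n_participants = n_participants, seed = as.integer(seed),
                 mode = mode, wave_offsets_years = wave_offsets_years,
                 group_probability = group_probability,
                 age_range = as.integer(age_range), age_decay = age_decay,
                 covariate_spec = covariate_spec,
                 true_intensities = true_intensities,
                 disease_onset_hazards = disease_onset_hazards,
                 baseline_prevalence = baseline_prevalence,
                 group_onset_hr = group_onset_hr,
                 onset_age_coef = onset_age_coef,
                 mortality = mortality,
                 horizon_years = horizon_years),
            class = "simulation_config")
}

#' Default marginal specs for baseline covariates
#'
#' Marginals loosely follow the covariate mix of a middle-aged and older
#' Chinese household panel: about half men, ~58% urban, mostly partnered,
#' education concentrated below upper secondary, and log-normal household
#' per-capita consumption.
#' @return named list of covariate specs.
#' @export
default_covariate_spec <- function() {
  list(
    gender   = list(type = "binary", p = 0.51),          # 1 = man
    urban    = list(type = "binary", p = 0.58),
    partnered = list(type = "binary", p = 0.96),
    education = list(type = "categorical",
                     levels = c("less_lower_secondary",
                                "upper_secondary_vocational", "tertiary"),
                     probs = c(0.833, 0.146, 0.021)),
    social_participation = list(type = "binary", p = 0.50),
    physical_activity    = list(type = "binary", p = 0.65),
    drinking = list(type = "binary", p = 0.37),
    smoking  = list(type = "binary", p = 0.40),
    log_consumption = list(type = "lognormal", meanlog = 9.2, sdlog = 0.7)
  )
}

#' Default synthetic disease list and onset hazards
#'
#' Fourteen chronic-condition categories typical of an ageing-cohort survey
#' with annual onset hazards in the 0.004-0.03 range. Values are synthetic
#' calibration choices, not estimates from any survey.
#' @return named numeric vector of per-year onset hazards.
#' @export
default_onset_hazards <- function() {
  c(hypertension = 0.030, dyslipidemia = 0.022, diabetes = 0.014,
    cancer = 0.004, chronic_lung_disease = 0.012, liver_disease = 0.006,
    heart_disease = 0.016, stroke = 0.007, kidney_disease = 0.008,
    digestive_disease = 0.018, emotional_problem = 0.006,
    memory_related_disease = 0.005, arthritis = 0.028, asthma = 0.006)
}

.draw_baseline_age <- function(n, range, decay) {
  ages <- range[1L]:range[2L]
  probs <- exp(-decay * (ages - range[1L]))
  sample(ages, n, replace = TRUE, prob = probs / sum(probs))
}

.draw_covariates <- function(spec) {
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    out[[nm]] <- switch(s$type,
      binary = stats::rbinom(1L, 1L, s$p),
      categorical = sample(s$levels, 1L, prob = s$probs),
      lognormal = stats::rnorm(1L, s$meanlog, s$sdlog),
      stop("unknown covariate type: ", s$type))
  }
  out
}

#' Simulate one progressive trajectory from an intensity model
#'
#' Forward simulation of the continuous-time Markov chain by competing
#' exponential clocks: from the current state the time to the next jump is
#' exponential with rate equal to the total outflow, and the destination is
#' categorical with probabilities proportional to the per-transition
#' intensities. If the model has an `age` covariate, intensities are
#' piecewise-constant within 1-year steps with age updated annually.
#' Uses the current RNG stream.
#'
#' @param intensity_model an [intensity_model()].
#' @param covariates named values for the model's covariates (baseline
#'   `age` if the model uses age).
#' @param horizon_years positive follow-up horizon.
#' @param start_state starting living state index (default 1).
#' @return object of class `trajectory`: list with `jump_times` (increasing
#'   years since baseline), `states_after_jump` (state indices, strictly
#'   increasing), and `death_time` (or NA).
#' @export
simulate_individual_path <- function(intensity_model, covariates = NULL,
                                     horizon_years, start_state = 1L) {
  stopifnot(inherits(intensity_model, "intensity_model"))
  if (!is.numeric(horizon_years) || horizon_years <= 0)
    stop("horizon must be positive")
  covs <- intensity_model$covariates
  if (length(covs)) {
    miss <- setdiff(covs, names(covariates))
    if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(names(covariates), covs)
    if (length(extra)) covariates <- covariates[covs]
  }
  has_age <- "age" %in% covs
  ss <- intensity_model$state_space
  death <- ss$death
  z <- if (length(covs)) as.numeric(covariates[covs]) else numeric(0)
  names(z) <- covs

  t_now <- 0
  state <- as.integer(start_state)
  jump_times <- numeric(0)
  states_after <- integer(0)
  death_time <- NA_real_
  # advance in 1-year blocks when age-dependent, otherwise one block
  step_end <- if (has_age) 1 else horizon_years
  Q <- build_intensity_matrix(intensity_model, z)
  repeat {
    if (t_now >= horizon_years || state == death) break
    rates <- Q[state, -state]
    total <- sum(rates)
    block_end <- min(step_end, horizon_years)
    if (total <= 0) {
      t_jump <- Inf
    } else {
      t_jump <- t_now + stats::rexp(1L, total)
    }
    if (t_jump <= block_end) {
      t_now <- t_jump
      cands <- seq_len(death)[-state]
      dest <- cands[sample.int(length(cands), 1L, prob = rates / total)]
      if (dest == death) {
        death_time <- t_now
        state <- death
      } else {
        jump_times <- c(jump_times, t_now)
        states_after <- c(states_after, dest)
        state <- dest
      }
    } else {
      t_now <- block_end
      if (has_age && t_now < horizon_years) {
        step_end <- step_end + 1
        z["age"] <- z["age"] + 1
        Q <- build_intensity_matrix(intensity_model, z)
      }
    }
  }
  structure(list(jump_times = jump_times, states_after_jump = states_after,
                 death_time = death_time, start_state = as.integer(start_state)),
            class = "trajectory")
}

#' Observe a trajectory at survey waves
#'
#' Produces one record per wave at which the participant is alive, carrying
#' the state occupied at that instant (the jump times themselves are not
#' recorded: interval censoring). A death occurring after the last living
#' observation adds exactly one record with the exact death time; no
#' records are produced after death.
#'
#' @param trajectory a [simulate_individual_path()] trajectory.
#' @param wave_offsets increasing wave times in years since baseline.
#' @return data frame with `wave`, `years_since_baseline`, `state`
#'   (integer), `vital_status` (`"alive"`/`"dead"`).
#' @export
observe_at_waves <- function(trajectory, wave_offsets) {
  if (any(diff(wave_offsets) <= 0)) stop("wave offsets must be increasing")
  dt <- trajectory$death_time
  start <- if (is.null(trajectory$start_state)) 1L else trajectory$start_state
  state_at <- function(t) {
    k <- sum(trajectory$jump_times <= t)
    if (k == 0L) start else trajectory$states_after_jump[k]
  }
  alive_waves <- if (is.na(dt)) seq_along(wave_offsets) else
    which(wave_offsets < dt)
  rec <- data.frame(
    wave = alive_waves - 1L,
    years_since_baseline = wave_offsets[alive_waves],
    state = vapply(wave_offsets[alive_waves], state_at, integer(1)),
    vital_status = "alive", stringsAsFactors = FALSE)
  if (!is.na(dt)) {
    rec <- rbind(rec, data.frame(
      wave = NA_integer_, years_since_baseline = dt,
      state = NA_integer_, vital_status = "dead", stringsAsFactors = FALSE))
  }
  rec
}

# piecewise-constant-hazard death time over [0, horizon]: breaks and rates
# of equal length; returns Inf if death does not occur
.piecewise_exp_draw <- function(breaks, rates, horizon) {
  t0 <- breaks
  t1 <- c(breaks[-1L], horizon)
  u <- stats::rexp(1L)  # unit-exponential threshold on cumulative hazard
  cumh <- 0
  for (i in seq_along(t0)) {
    seg <- (t1[i] - t0[i]) * rates[i]
    if (cumh + seg >= u)
      return(t0[i] + (u - cumh) / rates[i])
    cumh <- cumh + seg
  }
  Inf
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given the config seed: a single cohort-level stream draws
#' one sub-seed per participant, so each participant's draws are
#' reproducible independently of ordering. Returns the panel dataset (one
#' row per participant-wave, plus exact-dated death records) and the
#' ground-truth parameters used.
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (data frame) and `ground_truth` (list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_participants
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- stats::rbinom(n, 1L, config$group_probability)  # 1 = two-way
  dec <- config$age_decay
  ages <- integer(n)
  for (g in 0:1) {
    idx <- which(groups == g)
    ages[idx] <- .draw_baseline_age(length(idx), config$age_range,
                                    if (g == 1L) dec[["twoway"]] else dec[["downward"]])
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    cov_i <- .draw_covariates(config$covariate_spec)
    base <- data.frame(id = i, group = groups[i], age_baseline = ages[i],
                       stringsAsFactors = FALSE)
    for (nm in names(cov_i)) base[[nm]] <- cov_i[[nm]]
    if (config$mode == "state") {
      z <- c(group = groups[i], age = ages[i])
      traj <- simulate_individual_path(config$true_intensities, z,
                                       config$horizon_years)
      obs <- observe_at_waves(traj, config$wave_offsets_years)
      rows[[i]] <- cbind(base[rep(1L, nrow(obs)), , drop = FALSE], obs)
    } else {
      rows[[i]] <- .simulate_disease_participant(config, base, groups[i], ages[i])
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  gt <- list(mode = config$mode, seed = config$seed,
             n_participants = n,
             group_probability = config$group_probability,
             wave_offsets_years = config$wave_offsets_years)
  if (config$mode == "state") {
    gt$q0 <- as.numeric(config$true_intensities$q0)
    gt$transitions <- transition_names(config$true_intensities$state_space)
    gt$beta <- config$true_intensities$beta
    gt$covariates <- config$true_intensities$covariates
  } else {
    gt$disease_onset_hazards <- config$disease_onset_hazards
    gt$baseline_prevalence <- config$baseline_prevalence
    gt$group_onset_hr <- config$group_onset_hr
    gt$onset_age_coef <- config$onset_age_coef
    gt$mortality <- config$mortality
  }
  list(panel = panel, ground_truth = gt)
}

.simulate_disease_participant <- function(config, base, group, age) {
  hz <- config$disease_onset_hazards
  d <- length(hz)
  dn <- names(hz)
  horizon <- config$horizon_years
  prevalent <- stats::runif(d) < config$baseline_prevalence
  mult <- exp(config$onset_age_coef * (age - 60)) *
    if (group == 1L) config$group_onset_hr else 1
  onset <- ifelse(prevalent, 0, stats::rexp(d, pmax(hz * mult, 1e-12)))
  onset[hz * mult <= 0 & !prevalent] <- Inf
  # mortality: piecewise-constant in years, depends on age and current count
  mort <- config$mortality
  breaks <- sort(unique(c(0:ceiling(horizon), onset[onset > 0 & onset < horizon])))
  breaks <- breaks[breaks < horizon]
  count_at <- function(t) sum(onset <= t)
  rates <- vapply(breaks, function(t) {
    mort$base * exp(mort$age_coef * (age + t - 60) +
                    mort$count_coef * count_at(t))
  }, numeric(1))
  death <- .piecewise_exp_draw(breaks, rates, horizon)

  waves <- config$wave_offsets_years
  alive_waves <- which(waves < death)
  rec <- data.frame(
    wave = alive_waves - 1L,
    years_since_baseline = waves[alive_waves],
    vital_status = "alive", stringsAsFactors = FALSE)
  ind <- outer(waves[alive_waves], onset, ">=") + 0L
  colnames(ind) <- paste0("disease_", dn)
  rec <- cbind(rec, as.data.frame(ind))
  if (is.finite(death)) {
    dead <- rec[1L, , drop = FALSE]
    dead$wave <- NA_integer_
    dead$years_since_baseline <- death
    dead$vital_status <- "dead"
    dead[paste0("disease_", dn)] <- as.list(as.integer(onset <= death))
    rec <- rbind(rec, dead)
  }
  cbind(base[rep(1L, nrow(rec)), , drop = FALSE], rec)
}

#' Write / read a panel dataset as delimited text
#'
#' Comma-separated, one row per participant-wave record; a YAML side-car
#' stores ground truth when given.
#' @param panel panel data frame.
#' @param path CSV path.
#' @param ground_truth optional ground-truth list; written to
#'   `<path>.truth.yaml`.
#' @export
write_panel <- function(panel, path, ground_truth = NULL) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ground_truth)) {
    gt <- rapply(ground_truth, function(x) {
      if (is.matrix(x)) apply(x, 1L, as.numeric, simplify = FALSE) else x
    }, how = "replace")
    yaml::write_yaml(gt, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
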