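#' Configuration for the full analysis pipeline
#'
#' Bundles every analysis switch: simulation settings (or an input panel
#' path), the disease weight table, burden-state discretization, Cox and
#' multi-state options, and life-table conventions. The seed is recorded
#' in every output.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for all randomness.
#' @param n_participants synthetic cohort size (ignored when `panel_path`
#'   is given).
#' @param panel_path optional CSV of an existing panel dataset; when NULL
#'   a disease-mode cohort is simulated.
#' @param weight_table a `disease_weights` vector or a path to one;
#'   default the package's synthetic table.
#' @param k number of burden levels (default 5).
#' @param cluster_on `"observed"` (default: k-means on the observed
#'   person-wave index values, so the five levels reflect the burden
#'   actually carried by the cohort) or `"clusters"` (on the attainable
#'   cluster index values from exhaustive enumeration).
#' @param cox_covariates covariates for the Cox model.
#' @param msm_covariates covariates on transition intensities.
#' @param msm_covariate_transitions restriction of covariate effects to
#'   transitions (see [fit_multistate()]); the default puts the
#'   relationship-group effect on every transition and the age effect on
#'   transitions into death, where ageing acts most strongly.
#' @param transition_set `"full"` forward set or `"adjacent"` progression.
#' @param ties Cox tie method.
#' @param healthy_states healthy-state labels for HLE (default `"S1"`).
#' @param radix,omega,a_omega life-table conventions.
#' @param exclude_prevalent_msm drop participants whose baseline state is
#'   above S1 from the multi-state stage (default FALSE: they enter in
#'   their baseline state).
#' @param sim_args extra arguments passed to [simulation_config()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_participants = 6800L,
                            panel_path = NULL, weight_table = NULL,
                            k = 5L, cluster_on = c("observed", "clusters"),
                            cox_covariates = c("group", "age_baseline",
                                               "gender", "urban", "partnered",
                                               "education",
                                               "social_participation",
                                               "physical_activity", "drinking",
                                               "smoking", "log_consumption"),
                            msm_covariates = c("group", "age"),
                            msm_covariate_transitions = list(age = "death"),
                            transition_set = c("full", "adjacent"),
                            ties = c("efron", "breslow"),
                            healthy_states = "S1",
                            radix = 1e5, omega = 110L, a_omega = 0.5,
                            exclude_prevalent_msm = FALSE,
                            sim_args = list()) {
  cluster_on <- match.arg(cluster_on)
  transition_set <- match.arg(transition_set)
  ties <- match.arg(ties)
  if (is.null(weight_table)) {
    weight_table <- read_disease_weights(
      system.file("extdata", "disease_weights_synthetic.csv",
                  package = "morbstate"))
  } else if (is.character(weight_table)) {
    weight_table <- read_disease_weights(weight_table)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 panel_path = panel_path, weight_table = weight_table,
                 k = as.integer(k), cluster_on = cluster_on,
                 cox_covariates = cox_covariates,
                 msm_covariates = msm_covariates,
                 msm_covariate_transitions = msm_covariate_transitions,
                 transition_set = transition_set, ties = ties,
                 healthy_states = healthy_states, radix = radix,
                 omega = as.integer(omega), a_omega = a_omega,
                 exclude_prevalent_msm = exclude_prevalent_msm,
                 sim_args = sim_args),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load) the panel; Table-1-style
#' descriptives; burden index, exhaustive cluster enumeration and k-means
#' burden states; Cox model of time to multimorbidity with Kaplan-Meier
#' curves and Schoenfeld diagnostics; progressive multi-state model; and
#' per-group multistate life tables with LE, HLE and years of healthy life
#' lost. Every intermediate artifact is written to `out_dir` as delimited
#' text or YAML; reruns with the same config and seed are byte-identical.
#' A stage failure aborts with the stage name; artifacts of completed
#' stages persist.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a report bundle list with every stage's results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(config = config)
  opath <- function(f) file.path(out, f)

  # --- simulate / load -------------------------------------------------
  bundle$panel <- .stage("simulate", {
    if (!is.null(config$panel_path)) {
      read_panel(config$panel_path)
    } else {
      sim <- do.call(simulation_config,
                     c(list(n_participants = config$n_participants,
                            seed = config$seed, mode = "disease"),
                       config$sim_args))
      res <- simulate_cohort(sim)
      write_panel(res$panel, opath("panel.csv"), res$ground_truth)
      bundle$ground_truth <- res$ground_truth
      res$panel
    }
  })
  panel <- bundle$panel

  # --- descriptives ----------------------------------------------------
  bundle$descriptives <- .stage("descriptives", {
    base <- panel
    base$age_le_65 <- ifelse(base$age_baseline <= 65, "le_65", "gt_65")
    desc <- cohort_characteristics_table(
      base, "group",
      intersect(c("age_le_65", "gender", "partnered", "education", "urban",
                  "drinking", "smoking", "social_participation",
                  "physical_activity"), names(base)))
    utils::write.csv(desc, opath("descriptives.csv"), row.names = FALSE)
    desc
  })

  # --- burden index and states ----------------------------------------
  bundle$states <- .stage("burden_states", {
    dcols <- grep("^disease_", names(panel), value = TRUE)
    if (!length(dcols)) stop("panel has no disease_* columns")
    dnames <- sub("^disease_", "", dcols)
    w <- config$weight_table
    clusters <- enumerate_clusters(dnames, w)
    idx <- as.numeric(as.matrix(panel[dcols]) %*% as.numeric(w[dnames]))
    panel$burden_index <- idx
    panel$n_conditions <- rowSums(panel[dcols])
    fitvals <- if (config$cluster_on == "clusters") clusters$index else idx
    partition <- kmeans_1d(fitvals, config$k)
    write_partition(partition, opath("partition.yaml"))
    panel$state <- ifelse(panel$vital_status == "dead", NA_integer_,
                          match(assign_state(idx, partition),
                                paste0("S", seq_len(config$k))))
    utils::write.csv(panel, opath("state_panel.csv"), row.names = FALSE)
    list(clusters = clusters, partition = partition, panel = panel)
  })
  spanel <- bundle$states$panel

  # --- Cox -------------------------------------------------------------
  bundle$cox <- .stage("cox", {
    cc <- intersect(config$cox_covariates, names(spanel))
    tt <- derive_time_to_multimorbidity(spanel, cc)
    if (nrow(tt$records) == 0L || sum(tt$records$event) == 0L) {
      utils::write.csv(data.frame(note = "no events"),
                       opath("cox_hr.csv"), row.names = FALSE)
      list(note = "no events", records = tt$records)
    } else {
      km <- do.call(rbind, lapply(split(tt$records, tt$records$group),
        function(d) cbind(kaplan_meier(d), group = d$group[1L])))
      utils::write.csv(km, opath("km_curves.csv"), row.names = FALSE)
      fit <- fit_cox(tt$records, cc, ties = config$ties)
      hr <- cox_hr_table(fit)
      utils::write.csv(hr, opath("cox_hr.csv"), row.names = FALSE)
      ph <- schoenfeld_test(fit)
      yaml::write_yaml(list(
        seed = config$seed, n = fit$n, events = fit$n_event,
        converged = fit$converged, loglik = fit$loglik,
        ph_global_chisq = ph$global$chisq, ph_global_p = ph$global$p),
        opath("cox_fit.yaml"))
      list(records = tt, km = km, fit = fit, hr = hr, schoenfeld = ph)
    }
  })

  # --- multi-state model ----------------------------------------------
  bundle$msm <- .stage("multistate", {
    mp <- spanel
    if (config$exclude_prevalent_msm) {
      base1 <- mp$id[mp$years_since_baseline == 0 & !is.na(mp$state) &
                       mp$state == 1L]
      mp <- mp[mp$id %in% base1, , drop = FALSE]
    }
    ss <- state_space(config$k,
                      transitions = if (config$transition_set == "adjacent")
                        adjacent_transitions(config$k) else NULL)
    fit <- suppressWarnings(
      fit_multistate(mp, ss, covariate_names = config$msm_covariates,
                     covariate_transitions = config$msm_covariate_transitions))
    hr <- transition_hazard_ratio_table(fit, "group")
    utils::write.csv(hr, opath("transition_hr.csv"), row.names = FALSE)
    yaml::write_yaml(list(
      seed = config$seed, loglik = fit$loglik, converged = fit$converged,
      transitions = transition_names(fit$state_space),
      q0 = as.numeric(exp(fit$theta[seq_len(fit$ntr)]))),
      opath("msm_fit.yaml"))
    fit
  })

  # --- life tables -----------------------------------------------------
  bundle$life_tables <- .stage("life_table", {
    ages <- 45:(config$omega - 1L)
    tabs <- lapply(c(downward = 0, twoway = 1), function(g) {
      pm <- age_specific_probabilities(bundle$msm, ages,
                                       covariates = c(group = g),
                                       omega = config$omega)
      build_life_table(pm, radix = config$radix, start_age = 45,
                       a_omega = config$a_omega,
                       group = if (g == 0) "downward" else "twoway")
    })
    long <- do.call(rbind, lapply(tabs, life_table_long))
    utils::write.csv(long, opath("life_table.csv"), row.names = FALSE)
    summ <- do.call(rbind, lapply(tabs, life_expectancy_summary,
                                  healthy_states = config$healthy_states))
    utils::write.csv(summ, opath("life_expectancy.csv"), row.names = FALSE)
    list(tables = tabs, summary = summ)
  })

  # --- report ----------------------------------------------------------
  .stage("report", {
    s45 <- bundle$life_tables$summary
    s45 <- s45[s45$age == 45, , drop = FALSE]
    report <- list(
      seed = config$seed,
      n_participants = length(unique(panel$id)),
      group_split = as.list(table(panel$group[panel$years_since_baseline == 0])),
      cox_hr_group = if (!is.null(bundle$cox$hr))
        bundle$cox$hr$hr[bundle$cox$hr$term == "group"] else NA,
      le_at_45 = setNames(as.list(s45$LE), s45$group),
      hle_at_45 = setNames(as.list(s45$HLE), s45$group),
      years_lost_at_45 = setNames(as.list(s45$years_lost), s45$group))
    yaml::write_yaml(report, opath("report.yaml"))
    bundle$report <- report
  })
  invisible(bundle)
}
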