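#' Age-specific one-year transition probability matrices
#'
#' For each age x on the grid, evaluates the intensity matrix at that age
#' (other covariates fixed) and returns `P_x = exp(Q(age = x) * 1yr)`.
#'
#' @param model an [intensity_model()] with an `age` covariate, or a
#'   [fit_multistate()] result (its fitted model is used).
#' @param age_grid consecutive integer ages, within `[45, omega]`.
#' @param covariates named values for the model's other covariates.
#' @param omega upper age bound accepted (default 110).
#' @return named list of stochastic matrices, one per age.
#' @export
age_specific_probabilities <- function(model, age_grid, covariates = NULL,
                                       omega = 110) {
  if (inherits(model, "multistate_fit")) model <- model$model
  stopifnot(inherits(model, "intensity_model"))
  age_grid <- as.numeric(age_grid)
  if (any(age_grid != round(age_grid)) || any(diff(age_grid) != 1))
    stop("age grid must be consecutive integer years")
  if (min(age_grid) < 45 || max(age_grid) > omega)
    stop("ages must lie in [45, ", omega, "]")
  has_age <- "age" %in% model$covariates
  out <- lapply(age_grid, function(x) {
    z <- covariates
    if (has_age) z <- c(z, age = x)
    transition_probability(build_intensity_matrix(model, z), 1)
  })
  names(out) <- age_grid
  out
}

#' Build a multistate life table from per-age transition matrices
#'
#' Starting from a radix cohort distributed over living states at
#' `start_age`, occupancies advance as `l(x+1, .) = l(x, .) P_x` with the
#' death column absorbed into a cumulative-deaths track. Person-years use
#' the linear within-interval convention `L(x, s) = (l(x, s) +
#' l(x+1, s)) / 2`; at the closure age omega all survivors contribute
#' `a_omega` further years in their current state.
#'
#' @param p_matrices list of per-age transition matrices covering
#'   `[start_age, omega - 1]` (as from [age_specific_probabilities()]).
#' @param radix starting cohort size (default 100000).
#' @param start_age first age (default 45).
#' @param start_distribution occupancy fractions over living states at
#'   `start_age` (default all mass in S1).
#' @param a_omega average years lived at the closure age (default 0.5).
#' @param group optional group label carried into outputs.
#' @return object of class `multistate_life_table`: `ages`, occupancy
#'   matrix `l` (ages x living states, plus closure row), person-years
#'   `L`, cumulative deaths `deaths`, `radix`, `group`.
#' @export
build_life_table <- function(p_matrices, radix = 1e5, start_age = 45,
                             start_distribution = NULL, a_omega = 0.5,
                             group = NA_character_) {
  nages <- length(p_matrices)
  ns <- nrow(p_matrices[[1L]])
  n_living <- ns - 1L
  for (P in p_matrices) {
    if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8))
      stop("non-stochastic transition matrix in input")
  }
  if (is.null(start_distribution)) start_distribution <- c(1, rep(0, n_living - 1L))
  stopifnot(length(start_distribution) == n_living,
            abs(sum(start_distribution) - 1) < 1e-8)
  ages <- start_age + 0:nages
  l <- matrix(0, nages + 1L, n_living)
  deaths <- numeric(nages + 1L)
  l[1L, ] <- radix * start_distribution
  for (i in seq_len(nages)) {
    P <- p_matrices[[i]]
    nxt <- as.numeric(l[i, ] %*% P[seq_len(n_living), , drop = FALSE])
    l[i + 1L, ] <- nxt[seq_len(n_living)]
    deaths[i + 1L] <- deaths[i] + nxt[ns]
  }
  L <- (l[seq_len(nages), , drop = FALSE] + l[-1L, , drop = FALSE]) / 2
  L <- rbind(L, l[nages + 1L, ] * a_omega)   # closure row at omega
  labs <- colnames(p_matrices[[1L]])[seq_len(n_living)]
  if (is.null(labs)) labs <- paste0("S", seq_len(n_living))
  dimnames(l) <- list(ages, labs)
  dimnames(L) <- list(ages, labs)
  structure(list(ages = ages, l = l, L = L, deaths = deaths,
                 radix = radix, a_omega = a_omega, group = group),
            class = "multistate_life_table")
}

.lt_age_index <- function(lt, age) {
  i <- match(age, lt$ages)
  if (is.na(i)) stop("age ", age, " outside the life table range")
  i
}

#' Remaining life expectancy at an age
#'
#' `LE(x)` is total remaining person-years in living states from age x
#' divided by survivors at x.
#'
#' @param life_table a [build_life_table()] result.
#' @param age age in years (within the table).
#' @return years of remaining life expectancy.
#' @export
life_expectancy <- function(life_table, age) {
  i <- .lt_age_index(life_table, age)
  alive <- sum(life_table$l[i, ])
  if (alive <= 0) stop("no survivors at age ", age)
  sum(life_table$L[i:nrow(life_table$L), ]) / alive
}

#' Healthy life expectancy at an age
#'
#' `HLE(x)` counts only remaining person-years spent in the designated
#' healthy states; always `<= LE(x)`.
#'
#' @inheritParams life_expectancy
#' @param healthy_states character labels (or indices) of living states
#'   counted as healthy; must be a non-empty subset of the living states.
#' @return years of healthy life expectancy.
#' @export
healthy_life_expectancy <- function(life_table, age, healthy_states = "S1") {
  if (length(healthy_states) == 0L) stop("healthy state set must be non-empty")
  labs <- colnames(life_table$l)
  if (is.numeric(healthy_states)) healthy_states <- labs[healthy_states]
  bad <- setdiff(healthy_states, labs)
  if (length(bad)) stop("not living states: ", paste(bad, collapse = ", "))
  i <- .lt_age_index(life_table, age)
  alive <- sum(life_table$l[i, ])
  if (alive <= 0) stop("no survivors at age ", age)
  sum(life_table$L[i:nrow(life_table$L), healthy_states, drop = FALSE]) / alive
}

#' Years of healthy life lost to multimorbidity at an age
#'
#' The difference between life expectancy and healthy life expectancy.
#'
#' @inheritParams healthy_life_expectancy
#' @return non-negative years lost.
#' @export
years_lost <- function(life_table, age, healthy_states = "S1") {
  life_expectancy(life_table, age) -
    healthy_life_expectancy(life_table, age, healthy_states)
}

#' Tidy life-table export
#' @param life_table a `multistate_life_table`.
#' @return data frame (age, state, l, L, group) in plotting-ready form.
#' @export
life_table_long <- function(life_table) {
  labs <- colnames(life_table$l)
  out <- expand.grid(age = life_table$ages, state = labs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$l <- as.numeric(life_table$l)
  out$L <- as.numeric(life_table$L)
  out$group <- life_table$group
  out
}

#' Life-expectancy summary across ages
#' @param life_table a `multistate_life_table`.
#' @param ages ages to summarise (default every table age with survivors,
#'   excluding the closure age).
#' @param healthy_states healthy-state set (default `"S1"`).
#' @return data frame: age, LE, HLE, years_lost, group.
#' @export
life_expectancy_summary <- function(life_table, ages = NULL,
                                    healthy_states = "S1") {
  if (is.null(ages))
    ages <- life_table$ages[-length(life_table$ages)]
  ages <- ages[vapply(ages, function(a)
    sum(life_table$l[.lt_age_index(life_table, a), ]) > 0, logical(1))]
  le <- vapply(ages, function(a) life_expectancy(life_table, a), numeric(1))
  hle <- vapply(ages, function(a)
    healthy_life_expectancy(life_table, a, healthy_states), numeric(1))
  data.frame(age = ages, LE = le, HLE = hle, years_lost = le - hle,
             group = life_table$group, stringsAsFactors = FALSE)
}

#' @export
print.multistate_life_table <- function(x, ...) {
  cat("multistate life table: ages ", min(x$ages), "-", max(x$ages),
      ", radix ", x$radix,
      if (!is.na(x$group)) paste0(", group ", x$group), "\n", sep = "")
  cat("  LE(", min(x$ages), ") = ",
      round(life_expectancy(x, min(x$ages)), 3), " years\n", sep = "")
  invisible(x)
}
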