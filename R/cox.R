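#' Derive time-to-multimorbidity survival records from a panel dataset
#'
#' Time to multimorbidity is the difference between the time of second
#' diagnosis and baseline, with the second diagnosis dated by the wave at
#' which two or more conditions are first reported. Participants already
#' multimorbid at baseline are excluded (incident-case analysis);
#' participants never reaching two conditions are right-censored at their
#' last observation alive; deaths before multimorbidity are censored at the
#' exact death time.
#'
#' @param panel panel data frame with columns `id`, `years_since_baseline`,
#'   `vital_status`, and either a `n_conditions` column or `disease_*`
#'   indicator columns; baseline covariates are carried from the baseline
#'   record.
#' @param covariate_names covariate columns to carry into the records.
#' @return list with `records` (data frame: id, time, event, covariates),
#'   `excluded_baseline_multimorbid` (ids), and
#'   `excluded_no_followup` (ids censored at time 0).
#' @export
derive_time_to_multimorbidity <- function(panel, covariate_names = character()) {
  if (!"n_conditions" %in% names(panel)) {
    dcols <- grep("^disease_", names(panel), value = TRUE)
    if (!length(dcols)) stop("panel needs n_conditions or disease_* columns")
    panel$n_conditions <- rowSums(panel[dcols])
  }
  miss <- setdiff(covariate_names, names(panel))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  recs <- list(); excl_prev <- integer(0); excl_nofu <- integer(0)
  for (pid in unique(panel$id)) {
    pi <- panel[panel$id == pid, , drop = FALSE]
    pi <- pi[order(pi$years_since_baseline), , drop = FALSE]
    if (pi$years_since_baseline[1L] != 0)
      stop("participant ", pid, " has no baseline record")
    if (pi$n_conditions[1L] >= 2L) { excl_prev <- c(excl_prev, pid); next }
    alive <- pi[pi$vital_status == "alive", , drop = FALSE]
    hit <- which(alive$n_conditions >= 2L)
    if (length(hit)) {
      time <- alive$years_since_baseline[hit[1L]]; event <- 1L
    } else if (any(pi$vital_status == "dead")) {
      time <- pi$years_since_baseline[pi$vital_status == "dead"][1L]; event <- 0L
    } else {
      time <- alive$years_since_baseline[nrow(alive)]; event <- 0L
    }
    if (time <= 0) { excl_nofu <- c(excl_nofu, pid); next }
    row <- data.frame(id = pid, time = time, event = event,
                      stringsAsFactors = FALSE)
    for (cn in covariate_names) row[[cn]] <- pi[[cn]][1L]
    recs[[length(recs) + 1L]] <- row
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = integer(0), time = numeric(0), event = integer(0))
  rownames(records) <- NULL
  list(records = records,
       excluded_baseline_multimorbid = excl_prev,
       excluded_no_followup = excl_nofu)
}

#' Kaplan-Meier product-limit estimator with Greenwood variance
#'
#' @param records survival records data frame with `time` and `event`
#'   columns (optionally restricted to one group by the caller).
#' @param conf_type `"log-log"` (default) or `"plain"` 95% bands.
#' @return data frame with one row per distinct event/censoring time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `std_err`,
#'   `lower`, `upper`. The estimate is a right-continuous non-increasing
#'   step function starting at 1.
#' @export
kaplan_meier <- function(records, conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  if (nrow(records) == 0L) stop("empty group")
  ut <- sort(unique(records$time))
  n_risk <- n_event <- n_cens <- integer(length(ut))
  for (i in seq_along(ut)) {
    n_risk[i] <- sum(records$time >= ut[i])
    n_event[i] <- sum(records$time == ut[i] & records$event == 1L)
    n_cens[i] <- sum(records$time == ut[i] & records$event == 0L)
  }
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_event > 0, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(0.975)
  if (conf_type == "plain") {
    lower <- pmax(surv - z * se, 0); upper <- pmin(surv + z * se, 1)
  } else {
    # log(-log S) scale; undefined at S = 1 or 0
    ok <- surv > 0 & surv < 1
    selog <- rep(NA_real_, length(surv))
    selog[ok] <- sqrt(gw[ok]) / abs(log(surv[ok]))
    lower <- upper <- rep(NA_real_, length(surv))
    lower[ok] <- surv[ok]^exp(z * selog[ok])
    upper[ok] <- surv[ok]^exp(-z * selog[ok])
    lower[surv == 1] <- 1; upper[surv == 1] <- 1
    lower[surv == 0] <- 0; upper[surv == 0] <- 0
  }
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_cens, estimate = surv, std_err = se,
             lower = lower, upper = upper)
}

# Efron (or Breslow) log partial likelihood, gradient and information for
# coefficients beta. X: n x p, sorted arbitrary; returns list(ll, grad, info).
.cox_ll <- function(beta, time, event, X, ties = "efron") {
  n <- length(time); p <- ncol(X)
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ord <- order(-time)           # process decreasing time, accumulate risk set
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t_cur <- time[ord[i]]
    idx <- ord[i]
    while (i < n && time[ord[i + 1L]] == t_cur) { i <- i + 1L; idx <- c(idx, ord[i]) }
    i <- i + 1L
    for (j in idx) {            # all enter the risk set at t_cur
      S0 <- S0 + w[j]
      S1 <- S1 + w[j] * X[j, ]
      S2 <- S2 + w[j] * tcrossprod(X[j, ])
    }
    dead <- idx[event[idx] == 1L]
    d <- length(dead)
    if (d == 0L) next
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    T0 <- sum(w[dead])
    T1 <- colSums(w[dead] * X[dead, , drop = FALSE])
    T2 <- matrix(0, p, p)
    for (j in dead) T2 <- T2 + w[j] * tcrossprod(X[j, ])
    for (r in 0:(d - 1L)) {
      f <- if (ties == "efron") r / d else 0
      D0 <- S0 - f * T0
      D1 <- S1 - f * T1
      D2 <- S2 - f * T2
      m <- D1 / D0
      ll <- ll - log(D0)
      grad <- grad - m
      info <- info + D2 / D0 - tcrossprod(m)
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model by damped Newton iterations
#'
#' Maximises the Efron-tie-corrected log partial likelihood (Breslow
#' available via `ties`), with step-halving safeguards. Convergence is
#' declared when the score max-norm falls below `tol`; monotone likelihood
#' (perfect separation) is reported as non-convergence with a diagnostic.
#'
#' @param records survival records with `time`, `event` and covariate
#'   columns.
#' @param covariate_names covariates to include (character or factor
#'   columns are expanded to treatment-coded dummies).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol score max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `cox_fit`: coefficients, `vcov`, hazard ratios
#'   with 95% Wald bounds, log partial likelihood, score norm, iterations,
#'   convergence flag and the model frame pieces needed by
#'   [schoenfeld_test()].
#' @export
fit_cox <- function(records, covariate_names, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 100L) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1L) stop("no events in the data")
  X <- .model_matrix(records, covariate_names)
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate covariate(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  time <- records$time; event <- records$event
  beta <- numeric(p)
  cur <- .cox_ll(beta, time, event, X, ties)
  converged <- FALSE; diagnostic <- NULL
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) { diagnostic <- "singular information matrix"; break }
    fac <- 1
    repeat {
      cand <- beta + fac * step
      new <- .cox_ll(cand, time, event, X, ties)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) break
    }
    beta <- beta + fac * step
    cur <- new
    if (max(abs(beta)) > 25) {
      diagnostic <- "monotone likelihood (possible perfect separation)"
      break
    }
    # a vanishing Newton step means the optimum is resolved to machine
    # precision even if round-off keeps the score marginally above tol
    if (max(abs(fac * step)) < 1e-10) { converged <- TRUE; break }
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  vcov <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(0.975)
  names(beta) <- colnames(X)
  fit <- list(coefficients = beta, vcov = vcov, se = se,
              hr = exp(beta), hr_lower = exp(beta - z * se),
              hr_upper = exp(beta + z * se),
              wald_p = 2 * stats::pnorm(-abs(beta / se)),
              loglik = cur$ll, score_norm = max(abs(cur$grad)),
              iterations = it, converged = converged,
              diagnostic = diagnostic, ties = ties,
              n = nrow(X), n_event = sum(event),
              time = time, event = event, X = X)
  class(fit) <- "cox_fit"
  if (!converged)
    warning("Cox fit did not converge: ",
            if (is.null(diagnostic)) "iteration limit" else diagnostic)
  fit
}

.model_matrix <- function(records, covariate_names) {
  miss <- setdiff(covariate_names, names(records))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  cols <- list()
  for (cn in covariate_names) {
    v <- records[[cn]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      for (lev in levels(v)[-1L])
        cols[[paste0(cn, lev)]] <- as.numeric(v == lev)
    } else {
      cols[[cn]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$hr_lower, upper95 = x$hr_upper,
                    p = x$wald_p)
  print(signif(tab, 4))
  invisible(x)
}

#' Tidy table of hazard ratios from a Cox fit
#' @param fit a `cox_fit`.
#' @return data frame: term, coef, se, hr, lower, upper, p.
#' @export
cox_hr_table <- function(fit) {
  data.frame(term = names(fit$coefficients), coef = unname(fit$coefficients),
             se = unname(fit$se), hr = unname(fit$hr),
             lower = unname(fit$hr_lower), upper = unname(fit$hr_upper),
             p = unname(fit$wald_p), stringsAsFactors = FALSE)
}

#' Schoenfeld residual test of proportional hazards
#'
#' Computes per-event Schoenfeld residuals (Efron-adjusted risk-set means
#' under Efron ties), scales them by the inverse information, and tests a
#' zero slope against a transform of event time (Grambsch-Therneau score
#' test): per-covariate chi-square with 1 df and a global test with p df.
#'
#' @param fit a [fit_cox()] result.
#' @param transform `"rank"` (default; event-time ranks) or `"identity"`.
#' @return list with `table` (data frame: term, chisq, df, p), `global`
#'   (chisq, df, p), and the residual matrix.
#' @export
schoenfeld_test <- function(fit, transform = c("rank", "identity")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  p <- length(fit$coefficients)
  if (fit$n_event < 2L) stop("insufficient events for a proportional-hazards test")
  if (fit$n_event <= p) stop("fewer events than covariates")
  res <- .schoenfeld_residuals(fit)
  r <- res$resid            # d x p, ordered by event time
  etimes <- res$time
  d <- nrow(r)
  g <- if (transform == "rank") rank(etimes, ties.method = "average") else etimes
  g <- g - mean(g)
  imat <- .cox_ll(fit$coefficients, fit$time, fit$event, fit$X, fit$ties)$info
  vinv <- solve(imat)
  u <- as.numeric(t(g) %*% r)               # p-vector score
  # Var(u) ~ sum(g^2) * imat / d  (average-information approximation)
  denom <- sum(g^2) / d
  chisq_j <- u^2 / (denom * diag(imat))
  global <- as.numeric(t(u) %*% vinv %*% u) / denom
  tab <- data.frame(term = names(fit$coefficients), chisq = chisq_j, df = 1,
                    p = stats::pchisq(chisq_j, 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  list(table = tab,
       global = list(chisq = global, df = p,
                     p = stats::pchisq(global, p, lower.tail = FALSE)),
       residuals = r, time = etimes, transform = transform)
}

# Schoenfeld residuals x_i - xbar(t_i); under Efron ties each tied death
# uses the average of the d Efron-weighted risk-set means.
.schoenfeld_residuals <- function(fit) {
  X <- fit$X; time <- fit$time; event <- fit$event
  w <- exp(as.numeric(X %*% fit$coefficients))
  n <- nrow(X); p <- ncol(X)
  ord <- order(-time)
  S0 <- 0; S1 <- numeric(p)
  out_t <- numeric(0); out_r <- NULL
  i <- 1L
  while (i <= n) {
    t_cur <- time[ord[i]]; idx <- ord[i]
    while (i < n && time[ord[i + 1L]] == t_cur) { i <- i + 1L; idx <- c(idx, ord[i]) }
    i <- i + 1L
    for (j in idx) { S0 <- S0 + w[j]; S1 <- S1 + w[j] * X[j, ] }
    dead <- idx[event[idx] == 1L]
    d <- length(dead)
    if (d == 0L) next
    T0 <- sum(w[dead]); T1 <- colSums(w[dead] * X[dead, , drop = FALSE])
    mbar <- numeric(p)
    for (r0 in 0:(d - 1L)) {
      f <- if (fit$ties == "efron") r0 / d else 0
      mbar <- mbar + (S1 - f * T1) / (S0 - f * T0)
    }
    mbar <- mbar / d
    for (j in dead) {
      out_t <- c(out_t, t_cur)
      out_r <- rbind(out_r, X[j, ] - mbar)
    }
  }
  o <- order(out_t)
  list(time = out_t[o], resid = out_r[o, , drop = FALSE])
}
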