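#' Progressive Markov multi-state model for interval-censored panel data
#'
#' Living burden states are observed only at survey waves (interval
#' censoring); deaths are exactly dated. The likelihood of a participant is
#' the product over consecutive observation pairs of the transition
#' probability `P_{s_i s_{i+1}}(dt; z)`, and an exactly-dated death at time
#' T after a last living observation in state r contributes
#' `sum_{s living} P_{r s}(T - t_last; z) q_{s,death}(z)`. With an `age`
#' covariate, intensities are piecewise-constant within 1-year steps and
#' age is updated annually, so interval probabilities are products of
#' one-year matrices.
#'
#' @name multistate-model
NULL

# Prepare panel data for likelihood evaluation: validates progressivity,
# aggregates living-living interval pairs into cells, and extracts death
# terms. Covariate "age" (from age_baseline + elapsed time) is tracked
# separately when age_update is on.
.msm_prepare <- function(panel, ss, covariate_names, age_update) {
  has_age <- "age" %in% covariate_names
  zcovs <- setdiff(covariate_names, if (age_update) "age" else character(0))
  if (has_age && !"age_baseline" %in% names(panel) && !"age" %in% names(panel))
    stop("age covariate requested but panel has no age_baseline/age column")
  miss <- setdiff(setdiff(zcovs, "age"), names(panel))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(panel$id)
  ivl <- list(); dth <- list(); zrows <- list()
  for (pid in ids) {
    pi <- panel[panel$id == pid, , drop = FALSE]
    pi <- pi[order(pi$years_since_baseline), , drop = FALSE]
    alive <- pi[pi$vital_status == "alive", , drop = FALSE]
    st <- as.integer(alive$state)
    if (any(diff(st) < 0))
      stop("participant ", pid, " has a decreasing observed state sequence; ",
           "the progressive model forbids reversal")
    age0 <- if ("age_baseline" %in% names(pi)) pi$age_baseline[1L] else
      if ("age" %in% names(pi)) pi$age[1L] else NA_real_
    z <- if (length(zcovs)) {
      vals <- lapply(zcovs, function(cn)
        if (cn == "age") age0 else pi[[cn]][1L])
      setNames(vals, zcovs)
    } else list()
    zrows[[length(zrows) + 1L]] <- as.data.frame(z, stringsAsFactors = FALSE)
    zi <- length(zrows)
    tt <- alive$years_since_baseline
    if (nrow(alive) >= 2L) {
      ivl[[length(ivl) + 1L]] <- data.frame(
        zi = zi, from = st[-length(st)], to = st[-1L],
        dt = diff(tt), age = age0 + tt[-length(tt)])
    }
    if (any(pi$vital_status == "dead")) {
      tdeath <- pi$years_since_baseline[pi$vital_status == "dead"][1L]
      if (nrow(alive) == 0L)
        stop("participant ", pid, " has a death record but no living observation")
      tlast <- tt[length(tt)]
      if (tdeath <= tlast) stop("participant ", pid,
                                ": death time not after last living observation")
      dth[[length(dth) + 1L]] <- data.frame(
        zi = zi, from = st[length(st)], dt = tdeath - tlast,
        age = age0 + tlast)
    }
  }
  zmat <- do.call(rbind, zrows)
  # collapse identical covariate rows
  if (length(zcovs)) {
    key <- do.call(paste, c(zmat, sep = "\r"))
    uk <- !duplicated(key)
    zid_map <- match(key, key[uk])
    zuniq <- zmat[uk, , drop = FALSE]
  } else {
    zid_map <- rep(1L, length(ids))
    zuniq <- data.frame(row.names = 1L)
  }
  intervals <- if (length(ivl)) do.call(rbind, ivl) else NULL
  deaths <- if (length(dth)) do.call(rbind, dth) else NULL
  if (!is.null(intervals)) {
    intervals$zi <- zid_map[intervals$zi]
    if (age_update && has_age) {
      if (any(intervals$dt != round(intervals$dt)))
        stop("annual age updating needs integer wave gaps")
      cellkey <- paste(intervals$zi, intervals$from, intervals$to,
                       intervals$dt, intervals$age)
    } else {
      intervals$age <- NA_real_
      cellkey <- paste(intervals$zi, intervals$from, intervals$to, intervals$dt)
    }
    agg <- intervals[!duplicated(cellkey), , drop = FALSE]
    agg$n <- as.numeric(table(factor(cellkey, levels = cellkey[!duplicated(cellkey)])))
    intervals <- agg
  }
  if (!is.null(deaths)) {
    deaths$zi <- zid_map[deaths$zi]
    if (!(age_update && has_age)) deaths$age <- NA_real_
  }
  prep <- list(ss = ss, zuniq = zuniq, zcovs = zcovs,
               has_age = has_age && age_update,
               covariate_names = covariate_names,
               intervals = intervals, deaths = deaths,
               n_participants = length(ids))
  if (prep$has_age) prep <- .msm_index_age(prep)
  prep
}

# Precompute, for the annually-updated age model, the unique (z-pattern,
# age) combinations whose one-year matrices are needed, the interval
# products over them, and per-death index paths — so each likelihood
# evaluation is pure arithmetic over these indices.
.msm_index_age <- function(prep) {
  iv <- prep$intervals; de <- prep$deaths
  combo_key <- character(0)
  add_combos <- function(zi, age) paste(zi, age)
  # interval products keyed by (zi, age, dt)
  prods <- NULL
  if (!is.null(iv)) {
    pk <- paste(iv$zi, iv$age, iv$dt)
    up <- !duplicated(pk)
    prods <- iv[up, c("zi", "age", "dt"), drop = FALSE]
    prod_id <- match(pk, pk[up])
  }
  mfull <- ffrac <- NULL
  if (!is.null(de)) {
    mfull <- floor(de$dt - 1e-12)
    ffrac <- de$dt - mfull
  }
  keys <- c(
    if (!is.null(prods)) unlist(lapply(seq_len(nrow(prods)), function(k)
      add_combos(prods$zi[k], prods$age[k] + seq_len(prods$dt[k]) - 1L))),
    if (!is.null(de)) unlist(lapply(seq_len(nrow(de)), function(k)
      add_combos(de$zi[k], de$age[k] + seq_len(mfull[k]) - 1L))),
    if (!is.null(de)) add_combos(de$zi, de$age + mfull))
  uk <- unique(keys)
  parts <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
  combos <- data.frame(zi = as.integer(parts[, 1L]),
                       age = as.numeric(parts[, 2L]))
  cid <- function(zi, age) match(paste(zi, age), uk)
  # covariate matrix per combo, in covariate_names order
  Zc <- matrix(0, nrow(combos), length(prep$covariate_names),
               dimnames = list(NULL, prep$covariate_names))
  for (cn in prep$covariate_names) {
    Zc[, cn] <- if (cn == "age") combos$age else
      as.numeric(prep$zuniq[[cn]])[combos$zi]
  }
  if (!is.null(prods)) {
    prods$cids <- lapply(seq_len(nrow(prods)), function(k)
      cid(prods$zi[k], prods$age[k] + seq_len(prods$dt[k]) - 1L))
    prep$intervals$prod_id <- prod_id
  }
  if (!is.null(de)) {
    prep$deaths$mfull <- mfull
    prep$deaths$ffrac <- ffrac
    prep$death_full_cids <- lapply(seq_len(nrow(de)), function(k)
      cid(de$zi[k], de$age[k] + seq_len(mfull[k]) - 1L))
    prep$deaths$frac_cid <- cid(de$zi, de$age + mfull)
  }
  prep$combos <- combos
  prep$Zc <- Zc
  prep$prods <- prods
  prep
}

# Core log-likelihood given baseline rates and beta for a prepared dataset.
.msm_loglik_core <- function(prep, model) {
  ss <- model$state_space
  ns <- ss$death
  eps <- 1e-300
  # Q per (zid [, age]); with annual updating cache one-year P per (zid, age)
  zu <- prep$zuniq
  nz <- max(1L, nrow(zu))
  ll <- 0
  getz <- function(zi, age = NULL) {
    z <- if (ncol(zu)) unlist(zu[zi, , drop = TRUE]) else numeric(0)
    z <- setNames(as.numeric(z), colnames(zu))
    if (!is.null(age)) z <- c(z, age = age)
    z
  }
  if (!prep$has_age) {
    Qs <- lapply(seq_len(nz), function(zi) build_intensity_matrix(model, getz(zi)))
    # interval cells: P per (zi, dt)
    if (!is.null(prep$intervals)) {
      iv <- prep$intervals
      pkey <- paste(iv$zi, iv$dt)
      up <- !duplicated(pkey)
      Plist <- lapply(which(up), function(k)
        .unif_P(Qs[[iv$zi[k]]], iv$dt[k]))
      names(Plist) <- pkey[up]
      pr <- vapply(seq_len(nrow(iv)), function(k)
        Plist[[pkey[k]]][iv$from[k], iv$to[k]], numeric(1))
      ll <- ll + sum(iv$n * log(pmax(pr, eps)))
    }
    if (!is.null(prep$deaths)) {
      de <- prep$deaths
      for (zi in unique(de$zi)) {
        sel <- de$zi == zi
        Q <- Qs[[zi]]
        v <- Q[, ns]; v[ns] <- 0   # death intensities per living state
        W <- .expm_action(Q, v, de$dt[sel])
        dens <- W[cbind(de$from[sel], seq_len(sum(sel)))]
        ll <- ll + sum(log(pmax(dens, eps)))
      }
    }
  } else {
    # annually-updated age: all needed one-year matrices at once from the
    # precomputed (z, age) combo index
    tr <- ss$transitions
    b <- model$beta
    b[is.na(b)] <- 0
    zcen <- sweep(prep$Zc[, model$covariates, drop = FALSE], 2L,
                  model$centers[model$covariates])
    qm <- model$q0 * exp(b %*% t(zcen))   # ntr x n_combos
    C <- nrow(prep$combos)
    Qs <- vector("list", C)
    Qarr <- array(0, c(ns, ns, C))
    for (cc in seq_len(C)) {
      Q <- matrix(0, ns, ns)
      Q[tr] <- qm[, cc]
      diag(Q) <- -rowSums(Q)
      Qs[[cc]] <- Q
      Qarr[, , cc] <- Q
    }
    P1 <- .unif_P_stack(Qarr, 1)
    if (!is.null(prep$intervals)) {
      iv <- prep$intervals
      prods <- prep$prods
      Pp <- vector("list", nrow(prods))
      for (k in seq_len(nrow(prods))) {
        cids <- prods$cids[[k]]
        P <- P1[[cids[1L]]]
        for (y in cids[-1L]) P <- P %*% P1[[y]]
        Pp[[k]] <- P
      }
      pr <- vapply(seq_len(nrow(iv)), function(k)
        Pp[[iv$prod_id[k]]][iv$from[k], iv$to[k]], numeric(1))
      ll <- ll + sum(iv$n * log(pmax(pr, eps)))
    }
    if (!is.null(prep$deaths)) {
      de <- prep$deaths
      nd <- nrow(de)
      U <- matrix(0, nd, ns)
      U[cbind(seq_len(nd), de$from)] <- 1
      for (k in seq_len(nd)) {
        for (y in prep$death_full_cids[[k]])
          U[k, ] <- U[k, ] %*% P1[[y]]
      }
      dens <- numeric(nd)
      for (fc in unique(de$frac_cid)) {
        sel <- which(de$frac_cid == fc)
        Q <- Qs[[fc]]
        v <- Q[, ns]; v[ns] <- 0
        W <- .expm_action(Q, v, de$ffrac[sel])
        dens[sel] <- .rowSums(U[sel, , drop = FALSE] * t(W), length(sel), ns)
      }
      ll <- ll + sum(log(pmax(dens, eps)))
    }
  }
  ll
}

#' Interval-censored panel log-likelihood of an intensity model
#'
#' @param model an [intensity_model()].
#' @param panel panel data frame with `id`, `years_since_baseline`,
#'   `state` (integer, NA on death rows), `vital_status`, covariate
#'   columns, and `age_baseline` when the model has an age covariate.
#' @param age_update logical: update the age covariate annually within
#'   intervals (piecewise-constant intensities); needs integer wave gaps.
#' @return log-likelihood value.
#' @export
panel_log_likelihood <- function(model, panel, age_update = TRUE) {
  stopifnot(inherits(model, "intensity_model"))
  prep <- .msm_prepare(panel, model$state_space, model$covariates, age_update)
  .msm_loglik_core(prep, model)
}

#' Fit the progressive multi-state model to panel data
#'
#' Maximises the interval-censored panel likelihood over baseline
#' log-intensities and log-linear covariate effects by quasi-Newton (BFGS)
#' iterations, with standard errors from the inverse finite-difference
#' observed information. Allowed transitions with no supporting observed
#' pair (no observed interval that could contain them) are dropped with a
#' warning before fitting.
#'
#' @param panel panel data frame (see [panel_log_likelihood()]).
#' @param state_space a [state_space()]; its transition set (possibly a
#'   restriction mask) defines the candidate transitions.
#' @param covariate_names covariates entering log-linearly on intensities;
#'   `"age"` (from `age_baseline` + elapsed years, centred at 60) is
#'   updated annually when `age_update` is TRUE.
#' @param covariate_transitions optional named list restricting which
#'   transitions each covariate acts on: names are covariate names, values
#'   integer indices into the retained transition rows, or the keywords
#'   `"death"` (transitions into death) / `"living"` (between living
#'   states). Default: all transitions for every covariate.
#' @param initial_values optional list with `q0` and/or `beta` start values.
#' @param age_update see [panel_log_likelihood()].
#' @param max_iter BFGS iteration cap.
#' @return object of class `multistate_fit` with the fitted
#'   [intensity_model()], parameter table, covariance, log-likelihood and
#'   convergence metadata.
#' @export
fit_multistate <- function(panel, state_space, covariate_names = character(),
                           covariate_transitions = NULL,
                           initial_values = NULL, age_update = TRUE,
                           max_iter = 500L) {
  stopifnot(inherits(state_space, "state_space"))
  prep <- .msm_prepare(panel, state_space, covariate_names, age_update)
  tr <- state_space$transitions
  death <- state_space$death

  # supported = an observed pair exists that could contain the transition
  iv <- prep$intervals; de <- prep$deaths
  supported <- vapply(seq_len(nrow(tr)), function(k) {
    r <- tr[k, 1L]; s <- tr[k, 2L]
    if (s == death) {
      (!is.null(de) && any(de$from <= r)) ||
        (!is.null(iv) && FALSE)
    } else {
      !is.null(iv) && any(iv$from <= r & iv$to >= s & iv$from < iv$to)
    }
  }, logical(1))
  if (!all(supported)) {
    drop_names <- paste0(state_space$labels[tr[!supported, 1L]], "->",
                         state_space$labels[tr[!supported, 2L]])
    warning("dropping unsupported transition(s): ",
            paste(drop_names, collapse = ", "))
    state_space <- state_space(state_space$n_living,
                               transitions = tr[supported, , drop = FALSE],
                               labels = state_space$labels[seq_len(state_space$n_living)])
    tr <- state_space$transitions
  }
  ntr <- nrow(tr)
  ncov <- length(covariate_names)
  mask <- matrix(TRUE, ntr, ncov, dimnames = list(NULL, covariate_names))
  if (!is.null(covariate_transitions)) {
    for (cn in names(covariate_transitions)) {
      sel <- covariate_transitions[[cn]]
      if (identical(sel, "death")) sel <- which(tr[, 2L] == death)
      else if (identical(sel, "living")) sel <- which(tr[, 2L] != death)
      mask[, cn] <- FALSE
      mask[sel, cn] <- TRUE
    }
  }
  centers <- setNames(numeric(ncov), covariate_names)
  if ("age" %in% covariate_names) centers["age"] <- 60

  # crude initial rates: direct observed pair counts over person-years at risk
  q0_init <- rep(1e-3, ntr)
  if (!is.null(iv) || !is.null(de)) {
    expo <- numeric(state_space$n_living)
    if (!is.null(iv)) for (k in seq_len(nrow(iv)))
      expo[iv$from[k]] <- expo[iv$from[k]] + iv$n[k] * iv$dt[k]
    if (!is.null(de)) for (k in seq_len(nrow(de)))
      expo[de$from[k]] <- expo[de$from[k]] + de$dt[k]
    for (k in seq_len(ntr)) {
      r <- tr[k, 1L]; s <- tr[k, 2L]
      cnt <- if (s == death) {
        if (is.null(de)) 0 else sum(de$from == r)
      } else {
        if (is.null(iv)) 0 else sum(iv$n[iv$from == r & iv$to == s])
      }
      if (expo[r] > 0 && cnt > 0) q0_init[k] <- cnt / expo[r]
    }
  }
  if (!is.null(initial_values$q0)) q0_init <- rep_len(initial_values$q0, ntr)
  beta_init <- matrix(0, ntr, ncov)
  if (!is.null(initial_values$beta)) beta_init[] <- initial_values$beta

  theta0 <- c(log(q0_init), beta_init[mask])
  npar <- length(theta0)
  unpack <- function(theta) {
    q0 <- exp(theta[seq_len(ntr)])
    beta <- matrix(0, ntr, ncov, dimnames = list(NULL, covariate_names))
    if (any(mask)) beta[mask] <- theta[ntr + seq_len(sum(mask))]
    intensity_model(state_space, q0, beta, covariate_names, centers = centers)
  }
  negll <- function(theta) {
    # numerically safeguarded: rates outside a per-year band plausible for
    # panel data, or runaway effects, get a smooth penalty wall instead of
    # overflowing the likelihood
    lq <- theta[seq_len(ntr)]
    bb <- theta[-seq_len(ntr)]
    pen <- sum(pmax(lq - log(20), 0)^2) + sum(pmax(-lq - 30, 0)^2) +
      sum(pmax(abs(bb) - 20, 0)^2)
    if (pen > 0) return(1e8 * (1 + pen))
    m <- unpack(theta)
    -(.msm_loglik_core(prep, m))
  }
  fd_grad <- function(theta) {
    # forward differences; the likelihood is smooth and cheap relative to
    # a central-difference sweep at this parameter count
    f0 <- negll(theta)
    h <- 1e-7 * pmax(abs(theta), 1)
    vapply(seq_along(theta), function(i) {
      tp <- theta
      tp[i] <- tp[i] + h[i]
      (negll(tp) - f0) / h[i]
    }, numeric(1))
  }
  # stage 1: baseline intensities only (covariate effects at their starts)
  if (any(mask)) {
    nb <- sum(mask)
    negll_q <- function(lq) negll(c(lq, theta0[ntr + seq_len(nb)]))
    opt_q <- stats::optim(theta0[seq_len(ntr)], negll_q, method = "BFGS",
                          control = list(maxit = 200L, reltol = 1e-9))
    theta0[seq_len(ntr)] <- opt_q$par
  }
  opt <- stats::optim(theta0, negll, gr = fd_grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-11))
  converged <- opt$convergence == 0L
  if (!converged)
    warning("multistate fit: optimizer did not report convergence (code ",
            opt$convergence, ")")
  H <- tryCatch(
    stats::optimHess(opt$par, negll,
                     control = list(ndeps = rep(1e-5, npar))),
    error = function(e) NULL)
  vcov <- if (is.null(H)) matrix(NA_real_, npar, npar) else
    tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  bad_se <- !all(is.finite(diag(vcov))) || any(diag(vcov) < 0)

  model <- unpack(opt$par)
  trn <- transition_names(state_space)
  # theta packs beta entries by mask in column-major order
  par_names <- c(paste0("logq0[", trn, "]"),
                 unlist(lapply(seq_len(ncov), function(j)
                   paste0("beta[", covariate_names[j], ",", trn[mask[, j]], "]"))))
  se <- sqrt(pmax(diag(vcov), 0))
  structure(list(model = model, state_space = state_space,
                 theta = setNames(opt$par, par_names),
                 se = setNames(se, par_names), vcov = vcov,
                 mask = mask, ntr = ntr,
                 loglik = -opt$value, converged = converged,
                 se_ok = !bad_se,
                 counts = opt$counts, n_participants = prep$n_participants,
                 covariate_names = covariate_names,
                 age_update = age_update),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat("progressive multi-state model fit: ", x$n_participants,
      " participants, logLik = ", signif(x$loglik, 8),
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  print(signif(cbind(estimate = x$theta, se = x$se), 4))
  invisible(x)
}

#' Per-transition hazard-ratio table for one covariate
#'
#' One row per retained transition carrying that covariate, with
#' `HR = exp(beta)`, Wald 95% CI and two-sided p-value. For the
#' relationship-group covariate the reference level is the downward group
#' (covariate 0).
#'
#' @param fit a [fit_multistate()] result.
#' @param covariate covariate name (default `"group"`).
#' @return data frame: transition, coef, se, hr, lower, upper, p.
#' @export
transition_hazard_ratio_table <- function(fit, covariate = "group") {
  stopifnot(inherits(fit, "multistate_fit"))
  j <- match(covariate, fit$covariate_names)
  if (is.na(j)) stop("covariate not in fit: ", covariate)
  trn <- transition_names(fit$state_space)
  rows <- which(fit$mask[, j])
  # position of beta[,j] entries within theta
  offs <- fit$ntr + if (j > 1) sum(fit$mask[, seq_len(j - 1L)]) else 0L
  idx <- offs + seq_along(rows)
  b <- fit$theta[idx]; s <- fit$se[idx]
  z <- stats::qnorm(0.975)
  data.frame(transition = trn[rows], coef = unname(b), se = unname(s),
             hr = exp(unname(b)),
             lower = exp(unname(b) - z * unname(s)),
             upper = exp(unname(b) + z * unname(s)),
             p = 2 * stats::pnorm(-abs(unname(b) / unname(s))),
             stringsAsFactors = FALSE)
}
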