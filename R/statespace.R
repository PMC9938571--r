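#' Progressive state space for multimorbidity burden levels
#'
#' Ordered living burden states (default S1..S5, higher = more severe) plus
#' an absorbing death state. The multimorbidity burden can only stay
#' constant or move to a more severe state, never reverse, so the allowed
#' transition set contains every (r, s) with living r < s, plus (r, death)
#' for every living r. A restriction mask can remove forward transitions
#' (e.g. adjacent-only progression).
#'
#' @param n_living number of living states (default 5).
#' @param transitions optional two-column integer matrix (from, to) of
#'   allowed transitions; defaults to the full forward set. All must satisfy
#'   from < to, to <= n_living + 1, and death (n_living + 1) is absorbing.
#' @param labels labels for living states (default `S1..S5`); death is
#'   labelled `death`.
#' @return object of class `state_space`.
#' @export
state_space <- function(n_living = 5L, transitions = NULL,
                        labels = paste0("S", seq_len(n_living))) {
  n_living <- as.integer(n_living)
  stopifnot(n_living >= 1L, length(labels) == n_living)
  death <- n_living + 1L
  if (is.null(transitions)) {
    transitions <- full_forward_transitions(n_living)
  } else {
    transitions <- as.matrix(transitions)
    storage.mode(transitions) <- "integer"
    if (ncol(transitions) != 2L) stop("transitions must have columns (from, to)")
    if (any(transitions[, 1L] >= transitions[, 2L]))
      stop("progressive model: every transition must satisfy from < to")
    if (any(transitions[, 1L] > n_living))
      stop("death state is absorbing: no transitions out of state ", death)
    if (any(transitions[, 2L] > death)) stop("transition target out of range")
    if (anyDuplicated(transitions)) stop("duplicate transitions")
  }
  colnames(transitions) <- c("from", "to")
  structure(list(n_living = n_living, death = death,
                 labels = c(labels, "death"), transitions = transitions),
            class = "state_space")
}

#' Full forward transition set
#' @param n_living number of living states.
#' @return two-column matrix of all (r, s), r < s living, plus (r, death).
#' @export
full_forward_transitions <- function(n_living) {
  death <- n_living + 1L
  tr <- NULL
  for (r in seq_len(n_living)) {
    to <- c(if (r < n_living) (r + 1L):n_living, death)
    tr <- rbind(tr, cbind(r, to))
  }
  colnames(tr) <- c("from", "to")
  tr
}

#' Adjacent-only progression transition set
#' @param n_living number of living states.
#' @return matrix of (r, r+1) steps plus (r, death) for every living r.
#' @export
adjacent_transitions <- function(n_living) {
  death <- n_living + 1L
  tr <- rbind(cbind(seq_len(n_living - 1L), 2:n_living),
              cbind(seq_len(n_living), death))
  colnames(tr) <- c("from", "to")
  tr[order(tr[, 1L], tr[, 2L]), , drop = FALSE]
}

transition_names <- function(ss) {
  paste0(ss$labels[ss$transitions[, "from"]], "->",
         ss$labels[ss$transitions[, "to"]])
}

#' @export
print.state_space <- function(x, ...) {
  cat("progressive state space:", x$n_living, "living states + death\n")
  cat("  allowed transitions:", paste(transition_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Log-linear transition intensity model
#'
#' Each allowed transition (r, s) has a baseline per-year intensity
#' `q0_rs > 0` and a log-linear covariate effect: with covariate vector z,
#' `q_rs(z) = q0_rs * exp(beta_rs . z)`, so `exp(beta)` is a per-transition
#' hazard ratio. The `age` covariate, if present, is handled specially by
#' the simulator and the panel likelihood: it is frozen within each 1-year
#' step and updated annually (piecewise-constant intensities in age).
#'
#' @param state_space a [state_space()].
#' @param q0 positive baseline intensities, one per allowed transition
#'   (recycled if scalar); order follows `state_space$transitions` rows.
#' @param beta matrix of covariate effects, `n_transitions x n_covariates`
#'   (or NULL for no covariates); `NA` entries mean the covariate does not
#'   act on that transition (treated as 0, not estimated when fitting).
#' @param covariates character vector of covariate names (columns of beta).
#' @param centers optional named numeric of covariate centering constants
#'   (subtracted from supplied values before applying beta); baselines
#'   `q0` then refer to covariates at their centers. Typically
#'   `c(age = 60)` so that `q0` is the rate at age 60.
#' @return object of class `intensity_model`.
#' @export
intensity_model <- function(state_space, q0, beta = NULL, covariates = character(),
                            centers = NULL) {
  stopifnot(inherits(state_space, "state_space"))
  ntr <- nrow(state_space$transitions)
  q0 <- rep_len(as.numeric(q0), ntr)
  if (any(!is.finite(q0)) || any(q0 < 0))
    stop("baseline intensities must be non-negative and finite")
  if (length(covariates) == 0L) {
    beta <- matrix(numeric(0), nrow = ntr, ncol = 0L)
  } else {
    if (is.null(beta)) beta <- matrix(0, ntr, length(covariates))
    beta <- as.matrix(beta)
    if (!all(dim(beta) == c(ntr, length(covariates))))
      stop("beta must be n_transitions x n_covariates")
  }
  colnames(beta) <- covariates
  cen <- setNames(numeric(length(covariates)), covariates)
  if (!is.null(centers)) cen[names(centers)] <- as.numeric(centers)
  structure(list(state_space = state_space, q0 = q0, beta = beta,
                 covariates = as.character(covariates), centers = cen),
            class = "intensity_model")
}

#' Build the transition intensity (rate) matrix for given covariates
#'
#' Fills allowed entries with `q0_rs * exp(beta_rs . z)`, sets the diagonal
#' to minus the row outflow, leaves disallowed entries at exactly 0, and
#' leaves the death row all zero (absorbing).
#'
#' @param model an [intensity_model()].
#' @param covariates named numeric vector with a value for every covariate
#'   of the model (extra names are ignored).
#' @return square rate matrix of dimension `n_living + 1`.
#' @export
build_intensity_matrix <- function(model, covariates = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  ss <- model$state_space
  ns <- ss$death
  p <- length(model$covariates)
  if (p > 0L) {
    if (is.null(covariates)) stop("covariate values required")
    miss <- setdiff(model$covariates, names(covariates))
    if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
    z <- as.numeric(covariates[model$covariates]) - model$centers
    b <- model$beta
    b[is.na(b)] <- 0
    q <- model$q0 * exp(as.numeric(b %*% z))
  } else {
    q <- model$q0
  }
  Q <- matrix(0, ns, ns, dimnames = list(ss$labels, ss$labels))
  Q[ss$transitions] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an elapsed time
#'
#' `P(t) = exp(Q t)` by scaling-and-squaring matrix exponential. Rows sum
#' to 1; tiny negative round-off is clamped to 0.
#'
#' @param rate_matrix square intensity matrix (rows sum to 0).
#' @param elapsed_years non-negative elapsed time in years.
#' @return stochastic matrix of the same dimension.
#' @export
transition_probability <- function(rate_matrix, elapsed_years) {
  if (length(elapsed_years) != 1L || !is.finite(elapsed_years) || elapsed_years < 0)
    stop("elapsed time must be a single non-negative number")
  if (elapsed_years == 0)
    return(diag(nrow(rate_matrix)) + 0 * rate_matrix)
  P <- as.matrix(Matrix::expm(rate_matrix * elapsed_years))
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(rate_matrix)
  P
}

# exp(Q t) for one or many stacked rate matrices, by uniformization:
# P = sum_k Pois(k; Lambda t) (I + Q/Lambda)^k with the truncated Poisson
# tail folded into the last term. Robust for the upper-triangular rate
# matrices of progressive models; compiled kernel.
.unif_P <- function(Q, t) {
  n <- nrow(Q)
  P <- .unif_P_many_cpp(as.numeric(Q), n, t)
  matrix(P, n, n)
}

# stacked variant: Qarr is an ns x ns x C array; returns a list of C
# probability matrices
.unif_P_stack <- function(Qarr, t) {
  ns <- dim(Qarr)[1L]
  C <- dim(Qarr)[3L]
  P <- .unif_P_many_cpp(as.numeric(Qarr), ns, t)
  lapply(seq_len(C), function(c)
    matrix(P[((c - 1L) * ns * ns + 1L):(c * ns * ns)], ns, ns))
}

# exp(Q t) %*% v for many t at once (ns x length(tvec) matrix), same
# uniformization series
.expm_action <- function(Q, v, tvec) {
  .expm_action_cpp(Q, as.numeric(v), as.numeric(tvec))
}
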