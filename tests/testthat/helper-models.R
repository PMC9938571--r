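# Shared builders for small test models and cohorts.

# 2-state space: one living state + death
ss_alive_dead <- function() state_space(1L, labels = "S1")

# 3-state progressive chain S1 -> S2 -> S3 (S3 = absorbing "death" slot)
ss_chain3 <- function() state_space(2L, transitions = cbind(c(1L, 2L), c(2L, 3L)))

# 3 living states + death, adjacent progression plus death from every state
ss_chain_death <- function() {
  state_space(3L, transitions = cbind(c(1L, 2L, 1L, 2L, 3L),
                                      c(2L, 3L, 4L, 4L, 4L)))
}

# default recovery-study model: known rates, protective group effect on the
# first progression step
recovery_model <- function(beta_group = log(0.83)) {
  b <- matrix(0, 5, 1)
  b[1L, 1L] <- beta_group
  intensity_model(ss_chain_death(), q0 = c(0.20, 0.15, 0.03, 0.06, 0.10),
                  beta = b, covariates = "group")
}

# brute-force optimal contiguous k-partition of sorted values (oracle for
# the k-means dynamic program)
brute_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (c in seq_len(ncol(splits))) {
    b <- c(0L, splits[, c], n)
    ss <- 0
    for (q in seq_len(k)) {
      seg <- x[(b[q] + 1L):b[q + 1L]]
      ss <- ss + sum((seg - mean(seg))^2)
    }
    best <- min(best, ss)
  }
  best
}

# tiny synthetic disease-mode cohort for plumbing tests
tiny_disease_cohort <- function(n = 120L, seed = 7L) {
  simulate_cohort(simulation_config(n, seed = seed, mode = "disease"))
}

# microsimulation oracle: advance `n` individuals through the same per-age
# one-year matrices, crediting half a person-year in each of the bracketing
# states (the life table's linear convention) and a_omega at closure
microsim_years <- function(p_matrices, n, healthy = 1L, a_omega = 0.5,
                           seed = 1) {
  set.seed(seed)
  ns <- nrow(p_matrices[[1L]])
  n_living <- ns - 1L
  state <- rep(1L, n)
  total <- healthy_y <- numeric(n)
  for (P in p_matrices) {
    alive <- state <= n_living
    if (!any(alive)) break
    nxt <- state
    for (s in seq_len(n_living)) {
      idx <- which(state == s)
      if (!length(idx)) next
      nxt[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = P[s, ])
    }
    total <- total + 0.5 * alive + 0.5 * (nxt <= n_living)
    healthy_y <- healthy_y + 0.5 * (state %in% healthy) +
      0.5 * (nxt %in% healthy)
    state <- nxt
  }
  alive <- state <= n_living
  total <- total + a_omega * alive
  healthy_y <- healthy_y + a_omega * (state %in% healthy & alive)
  list(total = total, healthy = healthy_y)
}

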