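#' Disease weight tables and the multimorbidity burden index
#'
#' The burden index of an individual is the sum of severity weights of the
#' chronic diseases they currently report. Weights are supplied by the user
#' (two-column CSV or YAML); the package ships a synthetic table for testing
#' only (`system.file("extdata", "disease_weights_synthetic.csv",
#' package = "morbstate")`), whose values are not taken from any published
#' severity index.
#'
#' @param weights named numeric vector (names are disease identifiers) or a
#'   two-column data frame (disease, weight).
#' @return a named numeric vector of class `disease_weights`.
#' @export
disease_weights <- function(weights) {
  if (is.data.frame(weights)) {
    if (ncol(weights) < 2L)
      stop("weight table needs two columns: disease, weight")
    w <- as.numeric(weights[[2L]])
    names(w) <- as.character(weights[[1L]])
    weights <- w
  }
  if (is.null(names(weights)) || anyNA(names(weights)) || any(names(weights) == ""))
    stop("all weights must be named by disease")
  if (anyDuplicated(names(weights)))
    stop("disease names must be unique")
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0))
    stop("all disease weights must be positive and finite")
  structure(as.numeric(setNames(weights, names(weights))),
            names = names(weights), class = "disease_weights")
}

#' Read a disease weight table from CSV or YAML
#'
#' @param path file path; `.yaml`/`.yml` files are parsed as a mapping of
#'   disease name to weight, anything else as two-column delimited text with
#'   a header.
#' @return a `disease_weights` vector.
#' @export
read_disease_weights <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    disease_weights(unlist(lst))
  } else {
    disease_weights(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

#' Compute the multimorbidity burden index of a disease set
#'
#' Sums the weights of the diseases present. The empty set has index 0.
#'
#' @param disease_set character vector of disease names (may be empty).
#' @param weights a `disease_weights` vector covering every named disease.
#' @return non-negative scalar index value.
#' @export
compute_burden_index <- function(disease_set, weights) {
  disease_set <- as.character(disease_set)
  if (length(disease_set) == 0L) return(0)
  unknown <- setdiff(disease_set, names(weights))
  if (length(unknown))
    stop("disease(s) not in weight table: ", paste(unknown, collapse = ", "))
  sum(weights[unique(disease_set)])
}

#' Count conditions and flag multimorbidity
#'
#' Multimorbidity is the presence of two or more concurrent chronic diseases.
#'
#' @param disease_set character vector of disease names.
#' @return list with `count` and logical `multimorbid` (count >= 2).
#' @export
count_conditions <- function(disease_set) {
  n <- length(unique(as.character(disease_set)))
  list(count = n, multimorbid = n >= 2L)
}

#' Exhaustively enumerate disease clusters and their index values
#'
#' Lists every subset ("cluster") of the disease list, including the empty
#' set, with its burden index. Subsets are emitted in deterministic order:
#' the i-th row (0-based) is the subset whose binary representation of i
#' selects diseases, bit j (least significant first) selecting the j-th
#' disease in the order given.
#'
#' @param disease_names character vector of up to 20 disease names.
#' @param weights a `disease_weights` vector covering all names.
#' @return data frame with columns `cluster` (diseases joined by `+`, empty
#'   string for the empty set), `size`, and `index`; `2^d` rows.
#' @export
enumerate_clusters <- function(disease_names, weights) {
  disease_names <- as.character(disease_names)
  d <- length(disease_names)
  if (d > 20L)
    stop("refusing to enumerate more than 20 diseases (2^20 clusters); got ", d)
  if (anyDuplicated(disease_names)) stop("disease names must be unique")
  unknown <- setdiff(disease_names, names(weights))
  if (length(unknown))
    stop("disease(s) not in weight table: ", paste(unknown, collapse = ", "))
  n <- 2L^d
  if (d == 0L)
    return(data.frame(cluster = "", size = 0L, index = 0,
                      stringsAsFactors = FALSE))
  idx <- 0:(n - 1L)
  # membership matrix: n x d, bit j of i
  member <- matrix(FALSE, n, d)
  for (j in seq_len(d)) member[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L
  w <- as.numeric(weights[disease_names])
  index <- as.numeric(member %*% w)
  cluster <- vapply(seq_len(n), function(i) {
    paste(disease_names[member[i, ]], collapse = "+")
  }, character(1))
  data.frame(cluster = cluster, size = rowSums(member), index = index,
             stringsAsFactors = FALSE)
}

# Weighted sum-of-squares cost of values x[lo..hi] (sorted, with counts w),
# from prefix sums: cost = sum w x^2 - (sum w x)^2 / sum w.
.seg_cost <- function(cw, cwx, cwx2, lo, hi) {
  sw  <- cw[hi + 1L] - cw[lo]
  swx <- cwx[hi + 1L] - cwx[lo]
  sx2 <- cwx2[hi + 1L] - cwx2[lo]
  pmax(sx2 - swx^2 / sw, 0)
}

# Divide-and-conquer DP layer: for each i in [lo, hi], find the best last
# split j in [jlo, jhi] minimising prev[j - 1] + cost(j, i), exploiting that
# the optimal j is non-decreasing in i (concave Monge cost).
.dp_layer <- function(prev, cw, cwx, cwx2, lo, hi, jlo, jhi, cur, arg) {
  if (lo > hi) return(list(cur = cur, arg = arg))
  mid <- (lo + hi) %/% 2L
  js <- jlo:min(jhi, mid)
  vals <- prev[js - 1L] + .seg_cost(cw, cwx, cwx2, js, mid)
  b <- which.min(vals)
  cur[mid] <- vals[b]
  arg[mid] <- js[b]
  res <- .dp_layer(prev, cw, cwx, cwx2, lo, mid - 1L, jlo, js[b], cur, arg)
  .dp_layer(prev, cw, cwx, cwx2, mid + 1L, hi, js[b], jhi, res$cur, res$arg)
}

#' Exact one-dimensional k-means by dynamic programming
#'
#' Finds the globally optimal squared-error partition of real values into
#' `k` clusters. In one dimension optimal clusters are contiguous on the
#' sorted values, so dynamic programming over split points is exact and
#' deterministic; no random initialisation is involved.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of clusters (>= 2).
#' @return object of class `state_partition`: list with `boundaries` (k-1
#'   strictly increasing cut points, midpoints between adjacent-cluster
#'   extremes), `centroids` (cluster means, increasing), `within_ss`
#'   (total within-cluster sum of squares), `sizes` (points per cluster)
#'   and `k`.
#' @export
kmeans_1d <- function(values, k) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  ux <- sort(unique(values))
  m <- length(ux)
  if (m < k) stop("need at least k = ", k, " distinct values, got ", m)
  w <- as.numeric(tabulate(match(values, ux), nbins = m))
  cw   <- c(0, cumsum(w))
  cwx  <- c(0, cumsum(w * ux))
  cwx2 <- c(0, cumsum(w * ux^2))

  # dp[q][i]: optimal cost of first i unique values in q clusters
  prev <- .seg_cost(cw, cwx, cwx2, rep(1L, m), seq_len(m))
  args <- matrix(NA_integer_, k, m)
  for (q in 2:k) {
    res <- .dp_layer(prev, cw, cwx, cwx2, q, m, q, m,
                     rep(Inf, m), rep(NA_integer_, m))
    prev <- res$cur
    args[q, ] <- res$arg
  }

  # backtrack cluster start indices
  starts <- integer(k)
  i <- m
  for (q in k:2) {
    starts[q] <- args[q, i]
    i <- starts[q] - 1L
  }
  starts[1L] <- 1L
  ends <- c(starts[-1L] - 1L, m)

  centroids <- (cwx[ends + 1L] - cwx[starts]) / (cw[ends + 1L] - cw[starts])
  sizes <- cw[ends + 1L] - cw[starts]
  boundaries <- (ux[ends[-k]] + ux[starts[-1L]]) / 2
  structure(list(boundaries = boundaries, centroids = centroids,
                 within_ss = prev[m], sizes = as.integer(sizes), k = k),
            class = "state_partition")
}

#' Assign burden-state labels from a partition
#'
#' Intervals are half-open `[lower, upper)`: a value equal to a boundary is
#' assigned to the higher (more severe) state; the top interval is closed
#' above at infinity.
#'
#' @param index_value numeric vector of non-negative burden index values.
#' @param partition a `state_partition` from [kmeans_1d()].
#' @param labels optional state labels (default `S1..Sk`).
#' @return character vector of state labels.
#' @export
assign_state <- function(index_value, partition,
                         labels = paste0("S", seq_len(partition$k))) {
  stopifnot(inherits(partition, "state_partition"))
  x <- as.numeric(index_value)
  if (any(x < 0, na.rm = TRUE)) stop("burden index values must be non-negative")
  labels[findInterval(x, partition$boundaries) + 1L]
}

#' Export a state partition to YAML
#' @param partition a `state_partition`.
#' @param path output file path.
#' @export
write_partition <- function(partition, path) {
  yaml::write_yaml(list(boundaries = as.numeric(partition$boundaries),
                        centroids = as.numeric(partition$centroids),
                        within_ss = as.numeric(partition$within_ss),
                        k = partition$k), path)
  invisible(path)
}

#' @export
print.state_partition <- function(x, ...) {
  cat("1-D k-means partition, k =", x$k, "\n")
  cat("  boundaries:", paste(signif(x$boundaries, 6), collapse = ", "), "\n")
  cat("  centroids: ", paste(signif(x$centroids, 6), collapse = ", "), "\n")
  cat("  within-SS: ", signif(x$within_ss, 8), "\n")
  invisible(x)
}
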