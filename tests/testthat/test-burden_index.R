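test_that("burden index sums weights of present diseases", {
  w <- disease_weights(c(A = 1.5, B = 2.0, C = 0.7))
  expect_identical(compute_burden_index(character(0), w), 0)
  expect_equal(compute_burden_index(c("A", "B"), w), 3.5)
  expect_error(compute_burden_index(c("A", "X"), w), "not in weight table")
  # unit weights reduce the index to a disease count
  w14 <- disease_weights(setNames(rep(1, 14), paste0("d", 1:14)))
  expect_equal(compute_burden_index(paste0("d", 1:14), w14), 14)
})

test_that("multimorbidity flag requires two or more conditions", {
  expect_equal(count_conditions(character(0)), list(count = 0L, multimorbid = FALSE))
  expect_equal(count_conditions("A")$multimorbid, FALSE)
  expect_true(count_conditions(c("A", "B"))$multimorbid)
  expect_equal(count_conditions(c("A", "A", "B"))$count, 2L)
})

test_that("cluster enumeration is exhaustive, ordered, and monotone", {
  w <- disease_weights(c(A = 1, B = 2, C = 4))
  e <- enumerate_clusters(c("A", "B", "C"), w)
  expect_equal(nrow(e), 8L)
  # binary weights make every subset sum distinct: 0..7
  expect_equal(sort(e$index), 0:7)
  expect_equal(e$cluster[1L], "")
  expect_equal(e$index[1L], 0)
  # deterministic order: rerun identical
  expect_identical(e, enumerate_clusters(c("A", "B", "C"), w))

  w14 <- read_disease_weights(system.file("extdata",
    "disease_weights_synthetic.csv", package = "morbstate"))
  e14 <- enumerate_clusters(names(w14), w14)
  expect_equal(nrow(e14), 16384L)
  # inclusion monotonicity: a superset never has a smaller index; spot-check
  # each cluster against the same cluster plus the first absent disease
  set.seed(1)
  rows <- sample.int(16384L, 300L)
  for (r in rows) {
    present <- strsplit(e14$cluster[r], "+", fixed = TRUE)[[1L]]
    absent <- setdiff(names(w14), present)
    if (!length(absent)) next
    bigger <- compute_burden_index(c(present, absent[1L]), w14)
    expect_gte(bigger, e14$index[r])
  }
  expect_error(enumerate_clusters(paste0("d", 1:21), w),
               "more than 20 diseases")
})

test_that("1-D k-means dynamic program is globally optimal", {
  p <- kmeans_1d(c(0, 0, 10, 10), 2)
  expect_equal(p$within_ss, 0)
  expect_equal(p$boundaries, 5)
  p2 <- kmeans_1d(1:6, 2)
  expect_equal(p2$within_ss, 4)
  expect_equal(p2$centroids, c(2, 5))
  # k = number of distinct values: zero within-SS
  expect_equal(kmeans_1d(c(3, 1, 4, 1, 5), 4)$within_ss, 0)
  expect_error(kmeans_1d(c(1, 1, 2), 3), "distinct values")
  # exhaustive contiguous-partition oracle on random inputs
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(5:12, 1L)
    k <- sample(2:min(5L, n - 1L), 1L)
    x <- round(stats::runif(n, 0, 10), 2)
    if (length(unique(x)) < k) next
    dp <- kmeans_1d(x, k)$within_ss
    bf <- brute_kmeans_1d(x, k)
    # prefix-sum costs carry ~1e-12 cancellation noise on tiny segments
    expect_lt(abs(dp - bf), 1e-8 * (1 + bf))
  }
})

test_that("state assignment uses half-open intervals with ties going up", {
  p <- kmeans_1d(c(0, 1, 2, 5, 6, 9, 12, 15), 5)
  expect_equal(assign_state(0, p), "S1")
  expect_equal(assign_state(1e6, p), "S5")
  expect_equal(assign_state(p$boundaries[2L], p), "S3")
  expect_error(assign_state(-1, p), "non-negative")
})

test_that("index monotonicity propagates to non-decreasing states", {
  w <- read_disease_weights(system.file("extdata",
    "disease_weights_synthetic.csv", package = "morbstate"))
  set.seed(3)
  vals <- replicate(200, compute_burden_index(
    sample(names(w), sample.int(14, 1L)), w))
  p <- kmeans_1d(vals, 5)
  # growing disease sets along a trajectory give non-decreasing states
  for (rep in 1:20) {
    path <- sample(names(w), 6L)
    idx <- vapply(1:6, function(i) compute_burden_index(path[1:i], w), numeric(1))
    st <- match(assign_state(idx, p), paste0("S", 1:5))
    expect_true(all(diff(st) >= 0))
  }
})
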