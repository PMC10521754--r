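test_that("MMD^2 matches the brute-force double sum", {
  brute <- function(x, y, bw) {
    k <- function(a, b) exp(-(a - b)^2 / (2 * bw^2))
    s <- function(u, v) {
      acc <- 0
      for (a in u) for (b in v) acc <- acc + k(a, b)
      acc / (length(u) * length(v))
    }
    s(x, x) + s(y, y) - 2 * s(x, y)
  }
  set.seed(17)
  for (rep in 1:50) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1))
    bw <- runif(1, 0.3, 2)
    expect_equal(mmd_squared(x, y, bandwidth = bw), brute(x, y, bw),
                 tolerance = 1e-12)
  }
})

test_that("MMD^2 is symmetric, zero on identical samples and detects shift", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40, mean = 2); z <- rnorm(40)
  expect_equal(mmd_squared(x, y), mmd_squared(y, x), tolerance = 1e-14)
  expect_equal(mmd_squared(x, x), 0, tolerance = 1e-12)
  expect_gt(mmd_squared(x, y), mmd_squared(x, z))
})

test_that("point masses at 0 and 1 give the closed-form MMD^2", {
  # k(0,0)=k(1,1)=1, k(0,1)=exp(-1/(2 bw^2)); with bw=1: 2 - 2 exp(-0.5)
  expect_equal(mmd_squared(0, 1, bandwidth = 1), 2 - 2 * exp(-0.5),
               tolerance = 1e-14)
})

test_that("weighted MMD^2 equals replicating points by integer weights", {
  set.seed(8)
  x <- rnorm(5); y <- rnorm(4)
  wx <- c(3, 1, 2, 1, 1); wy <- c(2, 2, 1, 3)
  a <- mmd_squared(x, y, bandwidth = 0.8, wx = wx, wy = wy)
  b <- mmd_squared(rep(x, wx), rep(y, wy), bandwidth = 0.8)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the median heuristic is the median pairwise gap", {
  x <- c(0, 1, 3)
  # pairwise distances within the pooled sample: 1, 3, 2
  expect_identical(mmil:::median_bandwidth(x), 2)
})

test_that("selection recovers an informative dimension among noise", {
  sim <- make_gauss_bags(10, n_inst = 20, d = 8, shift_dims = 3,
                         shift = 1.5, seed = 21)
  sel <- select_feature_dims(sim$bags[sim$labels == 1],
                             sim$bags[sim$labels == 0], n_keep = 2)
  expect_true(3L %in% sel$kept_dims)
  expect_identical(which.max(sel$scores), 3L)
  expect_identical(sel$kept_dims, sort(sel$kept_dims))
})

test_that("selection defaults, degenerate dims and application contract hold", {
  sim <- make_gauss_bags(6, n_inst = 10, d = 6, shift_dims = 2, seed = 22)
  # a dimension that is constant everywhere must score zero
  bags <- lapply(sim$bags, function(b) {
    b$features[, 5] <- 7
    b
  })
  sel <- select_feature_dims(bags[sim$labels == 1], bags[sim$labels == 0])
  expect_identical(length(sel$kept_dims), 3L)   # default keeps half
  expect_identical(sel$scores[5], 0)
  expect_false(5L %in% sel$kept_dims)

  red <- apply_selection(bags[[1]], sel)
  expect_identical(ncol(red$features), 3L)
  expect_identical(red$features, bags[[1]]$features[, sel$kept_dims, drop = FALSE])
  wrong <- bags[[1]]
  wrong$features <- wrong$features[, 1:4, drop = FALSE]
  expect_error(apply_selection(wrong, sel), "fitted on")
})

test_that("histogram compression approximates the exact pooled MMD ranking", {
  sim <- make_gauss_bags(8, n_inst = 30, d = 4, shift_dims = 1,
                         shift = 2, seed = 23)
  pos <- sim$bags[sim$labels == 1]; neg <- sim$bags[sim$labels == 0]
  sel <- select_feature_dims(pos, neg, n_keep = 1)
  # exact (uncompressed) per-dimension MMD on the pooled instances
  pool <- function(bl, j) unlist(lapply(bl, function(b) b$features[, j]))
  exact <- vapply(1:4, function(j) mmd_squared(pool(pos, j), pool(neg, j)),
                  numeric(1))
  expect_identical(sel$kept_dims, which.max(exact))
  # full per-dimension ranking is preserved under compression
  expect_identical(order(sel$scores), order(exact))
  # the compressed score is the same order of magnitude as the exact one
  # (bandwidths differ: bin centers vs raw pooled sample)
  expect_gt(sel$scores[1] / exact[1], 0.5)
  expect_lt(sel$scores[1] / exact[1], 2)
})
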