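test_that("median bandwidth is the reciprocal median pairwise distance", {
  # scalar inputs {0, 1, 3}: distances 1, 2, 3 -> median 2
  expect_equal(median_bandwidth(c(0, 1, 3))$gamma, 0.5)
  # two points: the single distance is its own median
  expect_equal(median_bandwidth(c(0, 4))$gamma, 0.25)
  # 2-D input: Euclidean distances, not per-coordinate
  x <- cbind(c(0, 3, 6), c(0, 4, 8))
  expect_equal(median_bandwidth(x)$gamma, 1 / median(c(5, 10, 5)))
})

test_that("degenerate and invalid bandwidth inputs are handled", {
  res <- median_bandwidth(c(2, 2, 2))
  expect_equal(res$gamma, 1)
  expect_true(res$degenerate)
  expect_error(median_bandwidth(5), "2 samples")
  expect_error(median_bandwidth(c(1, NA)), "non-finite")
})

test_that("feature-wise bank has one unit-diagonal kernel per feature", {
  bank <- random_bank(20, 7, seed = 1)
  expect_length(bank$grams, 7)
  for (K in bank$grams) {
    expect_equal(unname(diag(K)), rep(1, 20))
    expect_true(all(K > 0 & K <= 1))
    expect_equal(K, t(K))
  }
  # explicit gram value: features {0, 1}, gamma = 1 -> off-diagonal exp(-1)
  b <- feature_wise_bank(matrix(c(0, 1), ncol = 1), gamma = 1)
  expect_equal(b$grams[[1]][1, 2], exp(-1))
})

test_that("bank sizes match the combinatorial counts for d in 2..8", {
  for (d in 2:8) {
    X <- matrix(runif(12 * d), 12, d)
    expect_length(feature_wise_bank(X)$grams, d)
    expect_length(pair_wise_bank(X, include_features = FALSE)$grams,
                  d * (d - 1) / 2)
    expect_length(pair_wise_bank(X)$grams, d + d * (d - 1) / 2)
  }
  expect_error(pair_wise_bank(matrix(runif(10), 10, 1)), "2 features")
})

test_that("pair-wise kernels are ordered lexicographically and 2-D", {
  X <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  bank <- pair_wise_bank(X, include_features = FALSE)
  expect_equal(bank$info$kernel, c("a:b", "a:c", "b:c"))
  # the (a, b) kernel must equal a Gaussian kernel on the 2-D block
  g <- bank$info$gamma[1]
  d2 <- unname(as.matrix(dist(X[, 1:2])))^2
  expect_equal(bank$grams[[1]], exp(-g * d2))
})

test_that("sub-kernel grams are PSD on random instances", {
  for (seed in 1:3) {
    bank <- random_bank(15, 4, seed = seed)
    for (K in bank$grams) {
      expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                -1e-8)
    }
  }
})

test_that("RKHS variance matches hand computations", {
  expect_equal(rkhs_variance(diag(2)), 0.5)          # 1 - 1/2
  expect_equal(rkhs_variance(matrix(1, 4, 4)), 0)    # constant feature
})

test_that("normalization yields unit RKHS variance and is idempotent", {
  bank <- random_bank(18, 5, seed = 2)
  norm1 <- normalize_bank(bank)
  for (K in norm1$grams) expect_equal(rkhs_variance(K), 1, tolerance = 1e-10)
  # identity gram of size N has sigma2 = 1 - 1/N (1/2 at N = 2)
  expect_equal(rkhs_variance(diag(2)), 0.5)
  b <- bank
  b$grams[[1]] <- diag(18)
  expect_equal(normalize_bank(b)$grams[[1]], diag(18) / (1 - 1 / 18))
  norm2 <- normalize_bank(norm1)
  expect_equal(norm2$grams, norm1$grams, tolerance = 1e-12)
})

test_that("zero-variance kernels are dropped, empty banks error", {
  X <- cbind(x1 = runif(10), x2 = rep(1, 10))
  bank <- feature_wise_bank(X)
  expect_warning(norm <- normalize_bank(bank), "x2")
  expect_equal(norm$info$kernel, "x1")
  Xc <- cbind(x1 = rep(2, 10))
  expect_error(suppressWarnings(normalize_bank(feature_wise_bank(Xc))),
               "degenerate bank")
})

test_that("combine_kernels is the weighted sum with validation", {
  bank <- normalize_bank(random_bank(12, 4, seed = 3))
  w <- c(0.3, 0, 1.2, 0.5)
  brute <- matrix(0, 12, 12)
  for (m in 1:4) brute <- brute + w[m] * bank$grams[[m]]
  expect_equal(combine_kernels(bank, w), brute)
  # one-hot returns the sub-kernel; zeros return the zero matrix
  expect_equal(combine_kernels(bank, c(0, 1, 0, 0)), bank$grams[[2]])
  expect_equal(combine_kernels(bank, rep(0, 4)), matrix(0, 12, 12))
  expect_error(combine_kernels(bank, c(1, 2)), "length")
  expect_error(combine_kernels(bank, c(-1, 0, 0, 0)), "negative")
})

test_that("cross-kernels reproduce training grams and reuse metadata", {
  set.seed(4)
  X <- matrix(runif(16 * 3, -0.5, 0.5), 16, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  bank <- normalize_bank(pair_wise_bank(X))
  cross <- cross_bank(bank, X, X)
  for (m in seq_along(cross)) {
    expect_equal(cross[[m]], bank$grams[[m]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a single test point equal to training point 5 reproduces row 5
  cross1 <- cross_bank(bank, X, X[c(5, 7), , drop = FALSE])
  expect_equal(cross1[[2]][1, ], bank$grams[[2]][5, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(cross_bank(bank, X, X[, 1:2]), "lacks feature")
})
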