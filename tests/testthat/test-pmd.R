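test_that("soft thresholding matches its printed definition", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  a <- c(-2.5, 0.1, 4, 0)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, max(abs(a))), rep(0, 4))
  expect_error(soft_threshold(a, -1), ">= 0")
})

test_that("l1_bound_delta finds the smallest sufficient threshold", {
  # (1, 0) is already a unit vector with L1 = 1
  expect_equal(l1_bound_delta(c(1, 0), 1), 0)
  # two equal entries normalize to L1 = sqrt(2) > 1, so Delta must bite;
  # thresholding cannot separate an exact tie, so the update resolves to
  # the lowest-index coordinate vector
  expect_gt(l1_bound_delta(c(1, 1), 1), 0)
  expect_equal(tskcca:::sparse_update(c(1, 1), 1), c(1, 0))
  # non-tied two-element case: the active budget pins the solution to the
  # L1 = c boundary with both entries alive
  w <- tskcca:::sparse_update(c(2, 1), 1.2)
  expect_equal(sum(abs(w)), 1.2, tolerance = 1e-6)
  expect_unit_l2(w)
  expect_equal(sum(w > 0), 2)
  # Cauchy-Schwarz: c = sqrt(M) never requires thresholding
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(6)
    expect_equal(l1_bound_delta(a, sqrt(6)), 0)
  }
  expect_error(l1_bound_delta(rep(0, 3), 1), "all-zero")
  expect_error(l1_bound_delta(c(1, 2), 0.5), ">= 1")
})

test_that("l1_bound_delta agrees with a brute-force grid oracle", {
  set.seed(20)
  for (i in 1:5) {
    a <- abs(rnorm(8))
    c <- runif(1, 1, sqrt(8) * 0.9)
    d <- l1_bound_delta(a, c)
    l1_at <- function(delta) {
      w <- soft_threshold(a, delta)
      s <- sqrt(sum(w^2))
      if (s == 0) 0 else sum(abs(w)) / s
    }
    expect_lte(l1_at(d), c + 1e-6)
    if (d > 1e-7) expect_gt(l1_at(d - 1e-7), c - 1e-6)
  }
})

test_that("rank-1 PMD solves the diagonal case exactly", {
  M <- diag(c(3, 1))
  p <- pmd_rank1(M, sqrt(2), sqrt(2))
  expect_equal(p$eta, c(1, 0), tolerance = 1e-8)
  expect_equal(p$mu, c(1, 0), tolerance = 1e-8)
  expect_equal(p$d, 3, tolerance = 1e-8)
})

test_that("budget 1 forces a single coordinate on each side", {
  set.seed(21)
  M <- matrix(runif(30, 0.1, 1), 6, 5)
  M[4, 2] <- 3  # clear max entry
  p <- pmd_rank1(M, 1, 1)
  expect_equal(sum(p$eta > 1e-8), 1)
  expect_equal(sum(p$mu > 1e-8), 1)
  expect_equal(which.max(p$eta), 4)
  expect_equal(which.max(p$mu), 2)
})

test_that("constraints hold and the objective is monotone over iterations", {
  set.seed(22)
  for (i in 1:4) {
    M <- matrix(runif(42, 0, 1), 7, 6)
    c1 <- runif(1, 1, sqrt(7)); c2 <- runif(1, 1, sqrt(6))
    p <- pmd_rank1(M, c1, c2)
    expect_unit_l2(p$eta)
    expect_unit_l2(p$mu)
    expect_true(all(p$eta >= 0) && all(p$mu >= 0))
    expect_lte(sum(p$eta), c1 + 1e-6)
    expect_lte(sum(p$mu), c2 + 1e-6)
    # monotonicity: replay the alternating updates and track eta' M mu
    eta <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (sum(eta) < 0) eta <- -eta
    eta <- pmax(eta, 0); eta <- eta / sqrt(sum(eta^2))
    obj_prev <- -Inf
    for (it in 1:25) {
      mu <- tskcca:::sparse_update(drop(crossprod(M, eta)), c2)
      eta <- tskcca:::sparse_update(drop(M %*% mu), c1)
      obj <- drop(t(eta) %*% M %*% mu)
      # slack reflects the Delta-bisection tolerance feeding each update
      expect_gte(obj, obj_prev - 1e-6)
      obj_prev <- obj
    }
  }
})

test_that("unconstrained budgets reproduce the dense SVD", {
  set.seed(23)
  M <- matrix(runif(30, 0.5, 1.5), 6, 5)
  sv <- svd(M)
  p <- pmd_rank1(M, sqrt(6), sqrt(5))
  expect_equal(p$d, sv$d[1], tolerance = 1e-6)
  expect_equal(abs(p$eta), abs(sv$u[, 1]), tolerance = 1e-5)
  expect_equal(abs(p$mu), abs(sv$v[, 1]), tolerance = 1e-5)
})

test_that("deflation recovers disjoint rank-k structure exactly", {
  # orthogonal non-negative factors with well separated scales
  u1 <- c(1, 1, 0, 0) / sqrt(2); v1 <- c(1, 0, 0)
  u2 <- c(0, 0, 1, 1) / sqrt(2); v2 <- c(0, 1, 0)
  M <- 5 * tcrossprod(u1, v1) + 2 * tcrossprod(u2, v2)
  ps <- pmd_decompose(M, 2, sqrt(3), n_components = 3)
  expect_equal(ps[[1]]$d, 5, tolerance = 1e-6)
  expect_equal(ps[[1]]$eta, u1, tolerance = 1e-6)
  expect_equal(ps[[2]]$d, 2, tolerance = 1e-6)
  expect_equal(ps[[2]]$mu, v2, tolerance = 1e-6)
  # residual after the true rank is numerically zero -> early stop
  expect_lte(length(ps), 3)
  R <- M - ps[[1]]$d * tcrossprod(ps[[1]]$eta, ps[[1]]$mu) -
    ps[[2]]$d * tcrossprod(ps[[2]]$eta, ps[[2]]$mu)
  expect_lt(sqrt(sum(R^2)), 1e-8)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(pmd_rank1(matrix(0, 3, 3), 1, 1), "all-zero")
  expect_error(pmd_rank1(diag(2), 0.5, 1), "outside")
  expect_error(pmd_decompose(diag(3), 1, 1, n_components = 5), "exceeds")
})
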