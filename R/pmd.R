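#' Element-wise soft-thresholding
#'
#' `sign(a) * (|a| - c)_+`: the proximal operator of the L1 penalty.
#'
#' @param a Numeric vector.
#' @param c Non-negative threshold.
#' @return Vector of the same length.
#' @export
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
soft_threshold <- function(a, c) {
  if (c < 0) abort("soft_threshold: threshold must be >= 0")
  sign(a) * pmax(abs(a) - c, 0)
}

#' Threshold level meeting an L1 budget after L2 normalization
#'
#' Finds, by bisection on `[0, max(|a|)]`, the smallest `Delta >= 0` such that
#' the L2-normalized soft-thresholded vector satisfies `||.||_1 <= c`. The
#' L1 norm of the normalized vector is non-increasing in `Delta`, which makes
#' bisection valid; `Delta = 0` is returned when the unthresholded normalized
#' vector already meets the budget (always the case for `c >= sqrt(length(a))`
#' by Cauchy-Schwarz).
#'
#' @param a Numeric vector, not all zero.
#' @param c L1 budget, `c >= 1` (a unit L2 vector has L1 at least 1).
#' @param tol Bisection tolerance on `Delta`.
#' @return Scalar `Delta`.
#' @export
l1_bound_delta <- function(a, c, tol = 1e-8) {
  if (c < 1) abort("l1_bound_delta: budget c must be >= 1")
  amax <- max(abs(a))
  if (amax == 0) abort("l1_bound_delta: degenerate all-zero vector")
  l1_of <- function(delta) {
    w <- soft_threshold(a, delta)
    s <- sqrt(sum(w^2))
    if (s == 0) 0 else sum(abs(w)) / s
  }
  if (l1_of(0) <= c) return(0)
  lo <- 0
  hi <- amax
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (l1_of(mid) > c) lo <- mid else hi <- mid
  }
  hi
}

# Clamp negatives to zero, soft-threshold to meet the L1 budget, then
# L2-normalize. Returns NULL if the iterate collapses to zero. Exactly tied
# maxima at a tight budget cannot be separated by soft-thresholding; that
# corner resolves to the coordinate vector of the lowest tied index, the
# sparsest feasible point.
sparse_update <- function(a, c) {
  a <- pmax(a, 0)
  if (max(a) <= 0) return(NULL)
  delta <- l1_bound_delta(a, c)
  w <- soft_threshold(a, delta)
  s <- sqrt(sum(w^2))
  if (s == 0) {
    w <- numeric(length(a))
    w[which.max(a)] <- 1
    return(w)
  }
  w / s
}

#' Rank-1 penalized matrix decomposition
#'
#' Maximizes `eta' M mu` over non-negative unit-L2 vectors subject to
#' `||eta||_1 <= c1`, `||mu||_1 <= c2`, by alternating soft-thresholded power
#' iterations: `mu <- normalize(S(M' eta, Delta2))` then
#' `eta <- normalize(S(M mu, Delta1))`, with each `Delta` set by
#' [l1_bound_delta()] and negative entries clamped to zero at every step.
#' `eta` is initialized from the dense leading left singular vector of `M`
#' (sign-flipped to non-negative orientation, then clamped). Deterministic
#' given `M`: no randomness is involved.
#'
#' @param M Numeric matrix (typically an HSIC matrix; deflated residuals may
#'   contain negative entries).
#' @param c1,c2 L1 budgets, in `[1, sqrt(nrow(M))]` and `[1, sqrt(ncol(M))]`.
#' @param init Optional initial `eta`; defaults to the SVD initializer.
#' @param max_iter,tol Convergence controls: stop when the largest absolute
#'   change in either vector falls below `tol`.
#' @return A list of class `singular_pair`: `eta`, `mu`, singular value
#'   `d = eta' M mu`, and iteration count.
#' @export
pmd_rank1 <- function(M, c1, c2, init = NULL, max_iter = 1000, tol = 1e-6) {
  if (!is.matrix(M) || length(M) == 0) abort("pmd_rank1: M must be a matrix")
  if (max(abs(M)) == 0) abort("pmd_rank1: M is all-zero")
  check_budget(c1, nrow(M), "c1")
  check_budget(c2, ncol(M), "c2")
  eta <- if (is.null(init)) {
    u <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (sum(u) < 0) u <- -u
    u <- pmax(u, 0)
    if (max(u) <= 0) u <- abs(u)
    u / sqrt(sum(u^2))
  } else {
    w <- pmax(init, 0)
    if (max(w) <= 0) abort("pmd_rank1: init clamps to zero")
    w / sqrt(sum(w^2))
  }
  mu <- rep(0, ncol(M))
  iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    mu_new <- sparse_update(drop(crossprod(M, eta)), c2)
    if (is.null(mu_new)) {
      abort("pmd_rank1: mu iterate collapsed to zero (budget infeasible for this M)")
    }
    eta_new <- sparse_update(drop(M %*% mu_new), c1)
    if (is.null(eta_new)) {
      abort("pmd_rank1: eta iterate collapsed to zero (budget infeasible for this M)")
    }
    delta <- max(max(abs(eta_new - eta)), max(abs(mu_new - mu)))
    eta <- eta_new
    mu <- mu_new
    if (delta < tol) break
  }
  structure(
    list(eta = eta, mu = mu, d = drop(crossprod(eta, M %*% mu)),
         iterations = iters),
    class = "singular_pair")
}

check_budget <- function(c, m, name) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c)) {
    abort(sprintf("%s must be a finite scalar", name))
  }
  if (c < 1 - 1e-9 || c > sqrt(m) + 1e-9) {
    abort(sprintf("%s = %.4g outside [1, sqrt(%d) = %.4g]",
                  name, c, m, sqrt(m)))
  }
  invisible(TRUE)
}

#' Successive sparse singular pairs by deflation
#'
#' Extracts `n_components` rank-1 pairs, subtracting `d * eta mu'` from `M`
#' after each fit. The residual may contain negative entries; non-negativity
#' applies to the weight vectors, never to the residual. Extraction stops
#' early when the residual's Frobenius norm vanishes.
#'
#' @inheritParams pmd_rank1
#' @param n_components Number of pairs, at most `min(dim(M))`.
#' @return List of `singular_pair` objects in extraction order.
#' @export
pmd_decompose <- function(M, c1, c2, n_components = 1,
                          max_iter = 1000, tol = 1e-6) {
  if (n_components > min(dim(M))) {
    abort(sprintf("n_components = %d exceeds min(dim(M)) = %d",
                  n_components, min(dim(M))))
  }
  out <- vector("list", n_components)
  R <- M
  for (i in seq_len(n_components)) {
    if (sqrt(sum(R^2)) < 1e-12) {
      out <- out[seq_len(i - 1)]
      break
    }
    p <- pmd_rank1(R, c1, c2, max_iter = max_iter, tol = tol)
    p$index <- i
    out[[i]] <- p
    R <- R - p$d * tcrossprod(p$eta, p$mu)
  }
  out
}
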