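#' Regularized kernel canonical correlation analysis
#'
#' Maximizes `alpha' Kx Kz beta` subject to the regularized normalizations
#' `alpha' (Kx + N kappa / 2 I)^2 alpha = 1` and the analogue for `beta`.
#' Solved via the whitened cross-operator: with `A = Kx + (N kappa / 2) I`
#' and `B = Kz + (N kappa / 2) I`, the leading singular pair `(u, v)` of
#' `R = A^{-1} Kx Kz B^{-1}` gives `alpha = A^{-1} u`, `beta = B^{-1} v` —
#' half the dimension of the raw `2N x 2N` generalized eigenproblem and
#' numerically stabler. Kernel matrices enter uncentered; the regularized
#' constraints keep the problem well-posed.
#'
#' @param Kx,Kz Combined `N x N` kernel matrices of the two views.
#' @param kappa Regularization, `> 0`; 0.02 is the conventional default for
#'   variance-normalized Gaussian kernels.
#' @return A list of class `kcca_model`: dual vectors `alpha`, `beta`,
#'   `kappa`, training canonical correlation `rho_train`, and the constraint
#'   residuals.
#' @export
fit_kcca <- function(Kx, Kz, kappa = 0.02) {
  if (!isTRUE(all.equal(dim(Kx), dim(Kz)))) abort("fit_kcca: dimension mismatch")
  if (any(!is.finite(Kx)) || any(!is.finite(Kz))) {
    abort("fit_kcca: non-finite kernel matrix")
  }
  if (!is.numeric(kappa) || kappa <= 0) abort("fit_kcca: kappa must be > 0")
  N <- nrow(Kx)
  r <- N * kappa / 2
  A <- Kx + diag(r, N)
  B <- Kz + diag(r, N)
  # both regularized kernels are symmetric positive definite: Cholesky solves
  cA <- tryCatch(chol(A), error = function(e) {
    abort(sprintf("fit_kcca: regularized x-kernel numerically singular (%s)",
                  conditionMessage(e)))
  })
  cB <- tryCatch(chol(B), error = function(e) {
    abort(sprintf("fit_kcca: regularized z-kernel numerically singular (%s)",
                  conditionMessage(e)))
  })
  chol_solve <- function(cU, Y) backsolve(cU, backsolve(cU, Y, transpose = TRUE))
  # R = (A^{-1} Kx) (B^{-1} Kz)' since Kz and B^{-1} are symmetric; its
  # leading right singular vector is the top eigenvector of R'R
  R <- chol_solve(cA, Kx) %*% t(chol_solve(cB, Kz))
  ev <- eigen(crossprod(R), symmetric = TRUE)
  v <- ev$vectors[, 1]
  u <- drop(R %*% v)
  d1 <- sqrt(sum(u^2))
  if (d1 < 1e-300) abort("fit_kcca: degenerate (zero) cross-operator")
  u <- u / d1
  alpha <- drop(chol_solve(cA, u))
  beta <- drop(chol_solve(cB, v))
  fx <- drop(Kx %*% alpha)
  gz <- drop(Kz %*% beta)
  rho <- cor(fx, gz)
  if (is.na(rho)) abort("fit_kcca: canonical variables have zero variance")
  if (rho < 0) {
    beta <- -beta
    rho <- -rho
  }
  res_a <- abs(drop(crossprod(A %*% alpha)) - 1)
  res_b <- abs(drop(crossprod(B %*% beta)) - 1)
  structure(
    list(alpha = alpha, beta = beta, kappa = kappa,
         rho_train = rho, objective = d1,
         constraint_residuals = c(alpha = res_a, beta = res_b)),
    class = "kcca_model")
}

#' @export
print.kcca_model <- function(x, ...) {
  cat(sprintf("<kcca_model> N = %d, kappa = %g, rho_train = %.4f\n",
              length(x$alpha), x$kappa, x$rho_train))
  invisible(x)
}

#' Canonical variable scores for new samples
#'
#' Evaluates `f(x) = sum_m w_m K_test^(m) alpha` on a list of cross-kernels
#' (see [cross_bank()]).
#'
#' @param cross_kernels List of `N_test x N_train` matrices.
#' @param weights Non-negative sub-kernel weights, one per cross-kernel.
#' @param dual Length-`N_train` dual coefficient vector.
#' @return Length-`N_test` numeric score vector.
#' @export
canonical_variables <- function(cross_kernels, weights, dual) {
  if (length(cross_kernels) != length(weights)) {
    abort("canonical_variables: weights do not match cross-kernel list")
  }
  scores <- numeric(nrow(cross_kernels[[1]]))
  for (m in which(weights > 0)) {
    Km <- cross_kernels[[m]]
    if (ncol(Km) != length(dual)) {
      abort("canonical_variables: dual length does not match training size")
    }
    scores <- scores + weights[m] * drop(Km %*% dual)
  }
  scores
}

#' Held-out canonical correlation of a fitted component
#'
#' Pearson correlation between the two test-sample canonical variable
#' vectors, built from cross-kernels that reuse the training bandwidths and
#' normalizations.
#'
#' @param model A `kcca_model`.
#' @param cross_x,cross_z Cross-kernel lists for the two views.
#' @param eta,mu The component's sub-kernel weight vectors.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
test_correlation <- function(model, cross_x, cross_z, eta, mu) {
  fx <- canonical_variables(cross_x, eta, model$alpha)
  gz <- canonical_variables(cross_z, mu, model$beta)
  if (sd(fx) < 1e-12 || sd(gz) < 1e-12) {
    abort("test_correlation: zero-variance canonical variables on test data")
  }
  cor(fx, gz)
}
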