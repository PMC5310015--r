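# Independent oracles used across the suite. Each re-derives a quantity by
# the most literal route available so the implementation under test never
# checks itself.

# HSIC by the textbook formula: build H explicitly, take the trace.
naive_hsic <- function(Kx, Kz) {
  n <- nrow(Kx)
  H <- diag(n) - matrix(1 / n, n, n)
  sum(diag(Kx %*% H %*% Kz %*% H)) / (n - 1)^2
}

# Full HSIC matrix by a double loop over naive_hsic.
naive_hsic_matrix <- function(bank_x, bank_z) {
  outer(seq_along(bank_x$grams), seq_along(bank_z$grams),
        Vectorize(function(m, l) naive_hsic(bank_x$grams[[m]],
                                            bank_z$grams[[l]])))
}

# Kernel CCA by the raw 2N x 2N generalized eigenproblem of the stationarity
# conditions, rescaled to satisfy the normalization constraints.
kcca_generalized_eigen <- function(Kx, Kz, kappa) {
  n <- nrow(Kx)
  r <- n * kappa / 2
  A <- rbind(cbind(matrix(0, n, n), Kx %*% Kz),
             cbind(Kz %*% Kx, matrix(0, n, n)))
  Breg <- rbind(cbind((Kx + diag(r, n)) %*% (Kx + diag(r, n)),
                      matrix(0, n, n)),
                cbind(matrix(0, n, n),
                      (Kz + diag(r, n)) %*% (Kz + diag(r, n))))
  ev <- eigen(solve(Breg, A))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  alpha <- v[1:n]
  beta <- v[(n + 1):(2 * n)]
  alpha <- alpha / sqrt(drop(t(alpha) %*% (Kx + diag(r, n)) %*%
                               (Kx + diag(r, n)) %*% alpha))
  beta <- beta / sqrt(drop(t(beta) %*% (Kz + diag(r, n)) %*%
                             (Kz + diag(r, n)) %*% beta))
  list(objective = abs(drop(t(alpha) %*% Kx %*% Kz %*% beta)),
       rho = abs(cor(drop(Kx %*% alpha), drop(Kz %*% beta))))
}

# Random PSD Gaussian-kernel banks on uniform features, for property checks.
random_bank <- function(n, d, seed, label = "x") {
  set.seed(seed)
  X <- matrix(runif(n * d, -0.5, 0.5), n, d)
  colnames(X) <- paste0(label, seq_len(d))
  feature_wise_bank(X, view_label = label)
}

expect_unit_l2 <- function(w, tol = 1e-8) {
  expect_equal(sqrt(sum(w^2)), 1, tolerance = tol)
}
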