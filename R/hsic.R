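#' Empirical Hilbert-Schmidt independence criterion of two kernels
#'
#' The plug-in estimator `Tr(Kx H Kz H) / (N - 1)^2`, where `H` is the
#' centering matrix with entries `delta_nn' - 1/N`. Non-negative for positive
#' semidefinite kernels, symmetric in its arguments, and zero against any
#' constant kernel.
#'
#' @param Kx,Kz `N x N` kernel matrices on the same samples.
#' @return Scalar dependence estimate.
#' @export
#' @examples
#' K <- matrix(c(1, 0.5, 0.5, 1), 2)
#' hsic(K, K)  # (1 - 0.5)^2 = 0.25
hsic <- function(Kx, Kz) {
  if (!all(dim(Kx) == dim(Kz))) {
    abort(sprintf("dimension mismatch: %dx%d vs %dx%d",
                  nrow(Kx), ncol(Kx), nrow(Kz), ncol(Kz)))
  }
  n <- nrow(Kx)
  if (n < 2) abort("hsic needs at least 2 samples")
  sum(center_gram(Kx) * center_gram(Kz)) / (n - 1)^2
}

# Double-center a gram matrix: H K H without forming H.
center_gram <- function(K) {
  K <- K - rowMeans(K)
  t(t(K) - colMeans(K))
}

# Flatten a bank's centered grams into an N^2 x M column matrix, so the whole
# HSIC matrix is one crossprod. Used by the permutation machinery too.
centered_flat <- function(bank) {
  n2 <- bank$n^2
  vapply(bank$grams, function(K) as.vector(center_gram(K)), numeric(n2))
}

#' HSIC matrix between two sub-kernel banks
#'
#' The `M_x x M_z` matrix whose `(m, l)` entry is [hsic()] of the m-th
#' x-sub-kernel and the l-th z-sub-kernel. Each gram is centered once and the
#' matrix assembled as a single cross-product; the result agrees with the
#' naive double loop to floating-point noise.
#'
#' @param bank_x,bank_z `subkernel_bank` objects sharing the sample set.
#' @return Numeric matrix with kernel identifiers as dimnames.
#' @export
hsic_matrix <- function(bank_x, bank_z) {
  stopifnot(inherits(bank_x, "subkernel_bank"),
            inherits(bank_z, "subkernel_bank"))
  if (length(bank_x$grams) == 0 || length(bank_z$grams) == 0) {
    abort("degenerate bank: no sub-kernels")
  }
  if (bank_x$n != bank_z$n) {
    abort(sprintf("banks are not sample-aligned: N = %d vs %d",
                  bank_x$n, bank_z$n))
  }
  M <- crossprod(centered_flat(bank_x), centered_flat(bank_z)) /
    (bank_x$n - 1)^2
  dimnames(M) <- list(bank_x$info$kernel, bank_z$info$kernel)
  M
}
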