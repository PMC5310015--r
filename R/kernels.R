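#' Median-heuristic Gaussian bandwidth
#'
#' Sets the inverse bandwidth of a Gaussian kernel from the data feeding it:
#' `gamma = 1 / median(pairwise Euclidean distances)`. The kernel is then
#' evaluated as `exp(-gamma * squared distance)`. For (near-)constant input,
#' where the median distance collapses, a fallback of `gamma = 1` is returned
#' and flagged.
#'
#' @param x Numeric vector or `N x d` matrix: the input of one sub-kernel
#'   (a single feature, or a feature pair as two columns).
#' @return A list with `gamma` and logical `degenerate`.
#' @export
#' @examples
#' median_bandwidth(c(0, 1, 3))$gamma  # distances 1,2,3 -> median 2 -> 0.5
median_bandwidth <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("median_bandwidth needs at least 2 samples")
  if (any(!is.finite(x))) abort("median_bandwidth: non-finite input")
  med <- median(dist(x))
  if (med < 1e-12) {
    list(gamma = 1, degenerate = TRUE)
  } else {
    list(gamma = 1 / med, degenerate = FALSE)
  }
}

# Gaussian gram matrix on an N x d input block.
gauss_gram <- function(x, gamma) {
  d2 <- unname(as.matrix(dist(x)))^2
  exp(-gamma * d2)
}

# Resolve the gamma policy for one sub-kernel input block.
resolve_gamma <- function(block, gamma, view_gamma) {
  if (is.numeric(gamma)) {
    list(gamma = gamma, degenerate = FALSE)
  } else if (identical(gamma, "median_per_view")) {
    view_gamma
  } else {
    median_bandwidth(block)
  }
}

new_bank <- function(grams, info, view, n, normalized = FALSE) {
  structure(
    list(grams = grams, info = info, view = view, n = n,
         normalized = normalized),
    class = "subkernel_bank")
}

#' @export
print.subkernel_bank <- function(x, ...) {
  cat(sprintf("<subkernel_bank> view '%s': %d kernels, N = %d, %s\n",
              x$view, length(x$grams), x$n,
              if (x$normalized) "normalized" else "unnormalized"))
  print(head(x$info, 5))
  invisible(x)
}

#' Build a bank of feature-wise Gaussian sub-kernels
#'
#' One `N x N` Gaussian gram matrix per feature,
#' `K[n, n'] = exp(-gamma * (x[n, m] - x[n', m])^2)`.
#'
#' @param view Numeric matrix or data frame (samples x features).
#' @param gamma Bandwidth policy: `"median_per_kernel"` (default; the median
#'   heuristic on each sub-kernel's own input), `"median_per_view"` (a single
#'   gamma from full-row Euclidean distances), or a fixed positive number.
#' @param view_label Label stored in the bank metadata.
#' @return A `subkernel_bank`.
#' @export
feature_wise_bank <- function(view, gamma = "median_per_kernel",
                              view_label = "x") {
  X <- as_view_matrix(view, view_label)
  vg <- if (identical(gamma, "median_per_view")) median_bandwidth(X) else NULL
  grams <- vector("list", ncol(X))
  info <- vector("list", ncol(X))
  for (m in seq_len(ncol(X))) {
    g <- resolve_gamma(X[, m, drop = FALSE], gamma, vg)
    grams[[m]] <- gauss_gram(X[, m, drop = FALSE], g$gamma)
    info[[m]] <- tibble::tibble(
      kernel = colnames(X)[m], type = "feature",
      f1 = colnames(X)[m], f2 = NA_character_,
      gamma = g$gamma, degenerate = g$degenerate)
  }
  new_bank(grams, dplyr::bind_rows(info), view_label, nrow(X))
}

#' Build a bank of pair-wise Gaussian sub-kernels
#'
#' One 2-D Gaussian sub-kernel per unordered feature pair `(m, m')`, `m < m'`,
#' in lexicographic order, capturing cross-feature interactions. By default
#' the `d` feature-wise sub-kernels are included ahead of the
#' `d * (d - 1) / 2` pair-wise ones, giving `d + d(d-1)/2` kernels in total;
#' set `include_features = FALSE` for the pairs alone.
#'
#' @inheritParams feature_wise_bank
#' @param include_features Prepend the feature-wise sub-kernels (default).
#' @return A `subkernel_bank`.
#' @export
pair_wise_bank <- function(view, gamma = "median_per_kernel",
                           view_label = "x", include_features = TRUE) {
  X <- as_view_matrix(view, view_label)
  if (ncol(X) < 2) abort("pair_wise_bank needs at least 2 features")
  vg <- if (identical(gamma, "median_per_view")) median_bandwidth(X) else NULL
  base <- if (include_features) {
    feature_wise_bank(X, gamma = gamma, view_label = view_label)
  } else {
    NULL
  }
  pairs <- utils::combn(ncol(X), 2)
  grams <- vector("list", ncol(pairs))
  info <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    m <- pairs[1, j]; m2 <- pairs[2, j]
    block <- X[, c(m, m2), drop = FALSE]
    g <- resolve_gamma(block, gamma, vg)
    grams[[j]] <- gauss_gram(block, g$gamma)
    info[[j]] <- tibble::tibble(
      kernel = paste0(colnames(X)[m], ":", colnames(X)[m2]), type = "pair",
      f1 = colnames(X)[m], f2 = colnames(X)[m2],
      gamma = g$gamma, degenerate = g$degenerate)
  }
  if (is.null(base)) {
    new_bank(grams, dplyr::bind_rows(info), view_label, nrow(X))
  } else {
    new_bank(c(base$grams, grams),
             dplyr::bind_rows(base$info, dplyr::bind_rows(info)),
             view_label, nrow(X))
  }
}

# Dispatch on the configured kernel mode.
build_bank <- function(view, mode = c("feature", "feature+pair", "pair"),
                       gamma = "median_per_kernel", view_label = "x") {
  mode <- match.arg(mode)
  switch(mode,
    "feature" = feature_wise_bank(view, gamma, view_label),
    "feature+pair" = pair_wise_bank(view, gamma, view_label,
                                    include_features = TRUE),
    "pair" = pair_wise_bank(view, gamma, view_label,
                            include_features = FALSE))
}

#' Variance of a sub-kernel's feature map in its RKHS
#'
#' The variance of the implicit feature vectors around their mean:
#' `sigma^2 = mean(diag(K)) - mean(K)`. Zero for a constant feature
#' (all-ones gram), one for a variance-normalized kernel.
#'
#' @param gram An `N x N` symmetric kernel matrix.
#' @return Non-negative scalar (tiny negative rounding is clamped at 0).
#' @export
rkhs_variance <- function(gram) {
  max(0, mean(diag(gram)) - mean(gram))
}

#' Normalize a sub-kernel bank to unit RKHS variance
#'
#' Divides every gram matrix by its [rkhs_variance()] so that all sub-kernels
#' contribute on a common scale when combined. Zero-variance sub-kernels
#' (constant features) cannot be rescaled and are dropped with a warning.
#'
#' @param bank A `subkernel_bank`.
#' @param tol Variance below which a kernel is treated as zero-variance.
#' @return The normalized bank; its `info` gains a `sigma2` column holding
#'   the pre-normalization variances.
#' @export
normalize_bank <- function(bank, tol = 1e-12) {
  stopifnot(inherits(bank, "subkernel_bank"))
  s2 <- vapply(bank$grams, rkhs_variance, numeric(1))
  keep <- s2 >= tol
  if (!all(keep)) {
    warn(sprintf("dropping %d zero-variance sub-kernel(s): %s",
                 sum(!keep),
                 paste(bank$info$kernel[!keep], collapse = ", ")))
  }
  if (!any(keep)) {
    abort("degenerate bank: all sub-kernels have zero RKHS variance")
  }
  grams <- purrr::map2(bank$grams[keep], s2[keep], ~ .x / .y)
  info <- bank$info[keep, , drop = FALSE]
  info$sigma2 <- s2[keep]
  new_bank(grams, info, bank$view, bank$n, normalized = TRUE)
}

#' Combine a sub-kernel bank with non-negative weights
#'
#' The multiple-kernel-learning combination `K = sum_m w_m K^(m)`.
#'
#' @param bank A `subkernel_bank`.
#' @param weights Non-negative numeric vector, one entry per sub-kernel.
#' @return An `N x N` symmetric positive semidefinite matrix.
#' @export
combine_kernels <- function(bank, weights) {
  stopifnot(inherits(bank, "subkernel_bank"))
  if (length(weights) != length(bank$grams)) {
    abort(sprintf("weight length %d != bank size %d",
                  length(weights), length(bank$grams)))
  }
  if (any(weights < 0)) abort("combine_kernels: negative weight")
  K <- matrix(0, bank$n, bank$n)
  for (m in which(weights > 0)) K <- K + weights[m] * bank$grams[[m]]
  K
}

#' Cross-kernels between test and training samples
#'
#' Evaluates each sub-kernel of a fitted (normalized) bank between new samples
#' and the training samples, reusing the training bandwidths and the training
#' RKHS-variance normalization — nothing is re-estimated from the test data.
#'
#' @param bank A normalized `subkernel_bank` fitted on the training view.
#' @param train_view,test_view The training and test view matrices; the test
#'   view must contain the training features (matched by name).
#' @return List of `N_test x N_train` matrices, aligned with `bank$info`.
#' @export
cross_bank <- function(bank, train_view, test_view) {
  stopifnot(inherits(bank, "subkernel_bank"))
  if (!bank$normalized) abort("cross_bank expects a normalized bank")
  Xtr <- as_view_matrix(train_view, bank$view)
  Xte <- as_view_matrix(test_view, paste0(bank$view, "_test"))
  need <- unique(c(bank$info$f1, bank$info$f2))
  need <- need[!is.na(need)]
  missing <- setdiff(need, colnames(Xte))
  if (length(missing) > 0) {
    abort(sprintf("test view lacks feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::pmap(bank$info, function(kernel, type, f1, f2, gamma, sigma2, ...) {
    cols <- if (is.na(f2)) f1 else c(f1, f2)
    a <- Xte[, cols, drop = FALSE]
    b <- Xtr[, cols, drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    exp(-gamma * d2) / sigma2
  })
}
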