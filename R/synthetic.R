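new_dataset <- function(X, Z, truth, params, test = NULL) {
  structure(
    list(X = tibble::as_tibble(as.data.frame(X)),
         Z = tibble::as_tibble(as.data.frame(Z)),
         truth = truth, params = params, test = test),
    class = "tskcca_dataset")
}

#' @export
print.tskcca_dataset <- function(x, ...) {
  cat(sprintf("<tskcca_dataset> %s: N = %d, p = %d, q = %d\n",
              x$params$dataset, nrow(x$X), ncol(x$X), ncol(x$Z)))
  cat("relevant x:", paste(x$truth$relevant_x, collapse = ", "), "\n")
  cat("relevant z:", paste(x$truth$relevant_z, collapse = ", "), "\n")
  invisible(x)
}

unif_mat <- function(n, d, prefix) {
  m <- matrix(runif(n * d, -0.5, 0.5), n, d)
  colnames(m) <- paste0(prefix, seq_len(d))
  m
}

#' Benchmark with a single quadratic association
#'
#' Draws all features uniformly on `[-0.5, 0.5]` and plants one nonlinear
#' link: `z1 = x1^2 + e`, `e ~ N(0, s^2)`. Only `x1` and `z1` are relevant;
#' linear CCA is blind to this even link on symmetric support, which is what
#' the benchmark probes.
#'
#' @param n Training samples.
#' @param d Features per view.
#' @param s Noise standard deviation.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param n_test Samples in an optional independent test split drawn from
#'   the same model.
#' @return A `tskcca_dataset`: tibbles `X`, `Z`, ground-truth `truth`
#'   (`relevant_x = "x1"`, `relevant_z = "z1"`), `params`, and `test`
#'   (list of `X`, `Z` tibbles) when `n_test > 0`.
#' @export
simulate_dataset1 <- function(n = 100, d = 10, s = 0.05, seed = NULL,
                              n_test = 0) {
  stopifnot(n >= 2, d >= 1, s >= 0)
  with_seed(seed, {
    gen <- function(n) {
      X <- unif_mat(n, d, "x")
      Z <- unif_mat(n, d, "z")
      Z[, 1] <- X[, 1]^2 + rnorm(n, 0, s)
      list(X = X, Z = Z)
    }
    tr <- gen(n)
    te <- if (n_test > 0) {
      g <- gen(n_test)
      list(X = tibble::as_tibble(as.data.frame(g$X)),
           Z = tibble::as_tibble(as.data.frame(g$Z)))
    }
    new_dataset(tr$X, tr$Z,
                truth = list(relevant_x = "x1", relevant_z = "z1"),
                params = list(dataset = "dataset1", n = n, d = d, s = s,
                              seed = seed, n_test = n_test),
                test = te)
  })
}

#' Benchmark with three additive nonlinear associations
#'
#' 25 uniform features per view; the first three z-features carry printed
#' two-feature links with noise `N(0, 0.1^2)`:
#' `z1 = x1 + exp(-x4^2)`, `z2 = x2^2 + sin(pi x5 / 2)`,
#' `z3 = |x3| + 1 / (1 + exp(-5 x6))`. Relevant features are `x1..x6` and
#' `z1..z3` (9 of the 50 feature-wise sub-kernels).
#'
#' @inheritParams simulate_dataset1
#' @return A `tskcca_dataset`.
#' @export
simulate_dataset2 <- function(n = 100, seed = NULL, n_test = 0) {
  stopifnot(n >= 2)
  d <- 25
  with_seed(seed, {
    gen <- function(n) {
      X <- unif_mat(n, d, "x")
      Z <- unif_mat(n, d, "z")
      Z[, 1] <- X[, 1] + exp(-X[, 4]^2) + rnorm(n, 0, 0.1)
      Z[, 2] <- X[, 2]^2 + sin(pi * X[, 5] / 2) + rnorm(n, 0, 0.1)
      Z[, 3] <- abs(X[, 3]) + 1 / (1 + exp(-5 * X[, 6])) + rnorm(n, 0, 0.1)
      list(X = X, Z = Z)
    }
    tr <- gen(n)
    te <- if (n_test > 0) {
      g <- gen(n_test)
      list(X = tibble::as_tibble(as.data.frame(g$X)),
           Z = tibble::as_tibble(as.data.frame(g$Z)))
    }
    new_dataset(tr$X, tr$Z,
                truth = list(relevant_x = paste0("x", 1:6),
                             relevant_z = paste0("z", 1:3)),
                params = list(dataset = "dataset2", n = n, d = d,
                              seed = seed, n_test = n_test),
                test = te)
  })
}

#' Benchmark with a cross-feature interaction
#'
#' Uniform features with one product link `z1 = x1 * x2 + e`,
#' `e ~ N(0, 0.1^2)`. Neither `x1` nor `x2` is marginally associated with
#' `z1`; only the pair-wise sub-kernel on `(x1, x2)` carries the signal, so
#' the ground truth names that pair (`"x1:x2"`) on the x side.
#'
#' @inheritParams simulate_dataset1
#' @return A `tskcca_dataset`.
#' @export
simulate_dataset3 <- function(n = 100, d = 10, seed = NULL, n_test = 0) {
  stopifnot(n >= 2, d >= 2)
  with_seed(seed, {
    gen <- function(n) {
      X <- unif_mat(n, d, "x")
      Z <- unif_mat(n, d, "z")
      Z[, 1] <- X[, 1] * X[, 2] + rnorm(n, 0, 0.1)
      list(X = X, Z = Z)
    }
    tr <- gen(n)
    te <- if (n_test > 0) {
      g <- gen(n_test)
      list(X = tibble::as_tibble(as.data.frame(g$X)),
           Z = tibble::as_tibble(as.data.frame(g$Z)))
    }
    new_dataset(tr$X, tr$Z,
                truth = list(relevant_x = "x1:x2", relevant_z = "z1"),
                params = list(dataset = "dataset3", n = n, d = d,
                              seed = seed, n_test = n_test),
                test = te)
  })
}

#' Precision and recall of sub-kernel selection
#'
#' Compares the sub-kernels retrieved by one or more components (those with
#' weight above `zero_tol`) against a dataset's ground-truth relevance
#' labels. Precision is the fraction of retrieved sub-kernels that are
#' relevant; recall is the fraction of relevant sub-kernels retrieved.
#' Precision is undefined (NA) when nothing is retrieved.
#'
#' @param fit A `tskcca` object.
#' @param truth A `tskcca_dataset` (or a list with `relevant_x`,
#'   `relevant_z` character vectors of sub-kernel identifiers).
#' @param components Which components' supports to pool (default: all).
#' @param zero_tol Weights at or below this are treated as zero.
#' @return Tibble: `precision`, `recall`, `n_retrieved`, `n_relevant`.
#' @export
score_selection <- function(fit, truth, components = NULL, zero_tol = 1e-8) {
  stopifnot(inherits(fit, "tskcca"))
  if (inherits(truth, "tskcca_dataset")) truth <- truth$truth
  comps <- fit$components
  if (!is.null(components)) comps <- comps[components]
  retrieved <- unique(unlist(purrr::map(comps, function(p) {
    c(fit$bank_x$info$kernel[p$eta > zero_tol],
      fit$bank_z$info$kernel[p$mu > zero_tol])
  })))
  relevant <- unique(c(truth$relevant_x, truth$relevant_z))
  hits <- length(intersect(retrieved, relevant))
  tibble::tibble(
    precision = if (length(retrieved) == 0) NA_real_ else
      hits / length(retrieved),
    recall = hits / length(relevant),
    n_retrieved = length(retrieved),
    n_relevant = length(relevant))
}
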