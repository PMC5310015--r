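#' Two-stage kernel CCA
#'
#' Runs the full pipeline on two sample-aligned views: build and normalize
#' Gaussian sub-kernel banks, assemble the HSIC dependence matrix between
#' them, extract sparse non-negative singular-vector pairs by penalized
#' matrix decomposition (selecting the L1 budgets by permutation grid search
#' when none are given), and fit regularized kernel CCA on each component's
#' weighted kernel combination. Optionally attaches permutation p-values per
#' component and held-out canonical correlations for a test split.
#'
#' @param X,Z Views: numeric matrices or data frames, one row per sample.
#' @param c1,c2 L1 sparsity budgets for the two weight vectors. When `NULL`,
#'   both are chosen by [grid_search_budget()].
#' @param n_components Number of singular-vector pairs to extract (capped at
#'   the HSIC matrix rank bound).
#' @param mode Sub-kernel design: `"feature"` (one kernel per feature),
#'   `"feature+pair"` (features plus all unordered feature pairs) or
#'   `"pair"`.
#' @param gamma Bandwidth policy, see [feature_wise_bank()].
#' @param kappa Kernel CCA regularization (default 0.02).
#' @param B Permutations for the grid search and for `pvalues = TRUE`.
#' @param seed Seed controlling all permutation draws.
#' @param grid,c_max Budget grid specification, see [grid_search_budget()].
#' @param test_X,test_Z Optional held-out views for test correlations.
#' @param pvalues Also run the component-wise permutation test?
#' @return An object of class `tskcca` with the banks, the HSIC matrix, the
#'   singular pairs, the per-component `kcca_model`s and a `results` tibble
#'   (component, singular value `d`, `rho_train`, optional `rho_test` and
#'   `p_value`).
#' @export
#' @examples
#' sim <- simulate_dataset1(n = 60, d = 4, s = 0.05, seed = 1)
#' fit <- tskcca(sim$X, sim$Z, c1 = 1, c2 = 1, n_components = 2)
#' tidy(fit)
tskcca <- function(X, Z, c1 = NULL, c2 = NULL, n_components = 10,
                   mode = "feature", gamma = "median_per_kernel",
                   kappa = 0.02, B = 100, seed = NULL, grid = NULL,
                   c_max = NULL, test_X = NULL, test_Z = NULL,
                   pvalues = FALSE) {
  state <- tk_prepare(X, Z, mode, gamma)
  selection <- NULL
  if (is.null(c1) || is.null(c2)) {
    selection <- grid_search_budget(grid = grid, c_max = c_max, B = B,
                                    seed = seed, kappa = kappa, state = state)
    c1 <- selection$c1
    c2 <- selection$c2
  }
  n_components <- min(n_components, dim(state$M))
  comps <- pmd_decompose(state$M, c1, c2, n_components)
  cross_x <- cross_z <- NULL
  if (!is.null(test_X) && !is.null(test_Z)) {
    test_X <- as_view_matrix(test_X, "test_x")
    test_Z <- as_view_matrix(test_Z, "test_z")
    check_aligned(test_X, test_Z)
    cross_x <- cross_bank(state$bank_x, state$X, test_X)
    cross_z <- cross_bank(state$bank_z, state$Z, test_Z)
  }
  models <- vector("list", length(comps))
  rho_train <- rho_test <- rep(NA_real_, length(comps))
  for (i in seq_along(comps)) {
    p <- comps[[i]]
    Kx <- combine_kernels(state$bank_x, p$eta)
    Kz <- combine_kernels(state$bank_z, p$mu)
    models[[i]] <- fit_kcca(Kx, Kz, kappa)
    rho_train[i] <- models[[i]]$rho_train
    if (!is.null(cross_x)) {
      rho_test[i] <- test_correlation(models[[i]], cross_x, cross_z,
                                      p$eta, p$mu)
    }
  }
  results <- tibble::tibble(
    component = seq_along(comps),
    d = vapply(comps, `[[`, numeric(1), "d"),
    rho_train = rho_train)
  if (!is.null(cross_x)) results$rho_test <- rho_test
  if (pvalues && length(comps) > 0) {
    pt <- permutation_test(state = state, c1 = c1, c2 = c2,
                           components = seq_along(comps), B = B,
                           seed = seed, kappa = kappa)
    results$p_value <- pt$p_value
  }
  structure(
    list(bank_x = state$bank_x, bank_z = state$bank_z, M = state$M,
         components = comps, models = models, results = results,
         c1 = c1, c2 = c2, selection = selection,
         config = list(mode = mode, gamma = gamma, kappa = kappa, B = B,
                       seed = seed, n_components = n_components,
                       n = state$n)),
    class = "tskcca")
}

#' @export
print.tskcca <- function(x, ...) {
  cat(sprintf(
    "<tskcca> N = %d, %d x %d sub-kernels, budgets (c1, c2) = (%.3f, %.3f)\n",
    x$config$n, nrow(x$M), ncol(x$M), x$c1, x$c2))
  print(x$results)
  invisible(x)
}

#' Dominant sub-kernel of each extracted component
#'
#' The singular value spectrum of the HSIC matrix can carry several
#' associations of nearly equal strength, so the extraction order of
#' components varies from draw to draw (label switching). This helper maps
#' each component to the sub-kernel carrying its largest weight on each
#' side, so components can be matched to the association they capture.
#'
#' @param fit A `tskcca` object.
#' @return Tibble: `component`, `x_top`, `x_top_weight`, `z_top`,
#'   `z_top_weight`.
#' @export
dominant_kernels <- function(fit) {
  stopifnot(inherits(fit, "tskcca"))
  purrr::map_dfr(fit$components, function(p) {
    ix <- which.max(p$eta)
    iz <- which.max(p$mu)
    tibble::tibble(
      component = p$index,
      x_top = fit$bank_x$info$kernel[ix], x_top_weight = p$eta[ix],
      z_top = fit$bank_z$info$kernel[iz], z_top_weight = p$mu[iz])
  })
}

#' Serialize a fitted model to JSON
#'
#' Writes the configuration echo, the selected budgets, and every
#' component's weight vectors (resolved to sub-kernel names), singular
#' value, training/test correlations and p-values.
#'
#' @param fit A `tskcca` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "tskcca"))
  comps <- purrr::map(fit$components, function(p) {
    row <- fit$results[fit$results$component == p$index, ]
    list(
      component = p$index, d = p$d,
      eta = setNames(as.list(p$eta), fit$bank_x$info$kernel),
      mu = setNames(as.list(p$mu), fit$bank_z$info$kernel),
      rho_train = row$rho_train,
      rho_test = if ("rho_test" %in% names(row)) row$rho_test else NULL,
      p_value = if ("p_value" %in% names(row)) row$p_value else NULL)
  })
  payload <- list(
    config = c(fit$config, list(c1 = fit$c1, c2 = fit$c2)),
    components = comps)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
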