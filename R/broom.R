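#' Tidy the sub-kernel weights of a fitted model
#'
#' One row per (component, sub-kernel): the sparse non-negative weight each
#' sub-kernel receives in each singular-vector pair, with its source
#' feature(s) resolved from the bank metadata.
#'
#' @param x A `tskcca` object.
#' @param zero_tol Drop rows with weight at or below this; set to `NULL` to
#'   keep the full (mostly zero) vectors.
#' @param ... Unused.
#' @return Tibble: `component`, `view`, `kernel`, `type`, `weight`.
#' @method tidy tskcca
#' @export
tidy.tskcca <- function(x, zero_tol = 1e-8, ...) {
  out <- purrr::map_dfr(x$components, function(p) {
    dplyr::bind_rows(
      tibble::tibble(component = p$index, view = "x",
                     kernel = x$bank_x$info$kernel,
                     type = x$bank_x$info$type, weight = p$eta),
      tibble::tibble(component = p$index, view = "z",
                     kernel = x$bank_z$info$kernel,
                     type = x$bank_z$info$type, weight = p$mu))
  })
  if (!is.null(zero_tol)) out <- dplyr::filter(out, .data$weight > zero_tol)
  out
}

#' One-row summary of a fitted model
#'
#' @param x A `tskcca` object.
#' @param ... Unused.
#' @return Tibble with the sample size, bank sizes, budgets, `kappa`, the
#'   number of components, the leading training correlation, and the
#'   smallest permutation p-value when available.
#' @method glance tskcca
#' @export
glance.tskcca <- function(x, ...) {
  tibble::tibble(
    n = x$config$n,
    m_x = nrow(x$M), m_z = ncol(x$M),
    c1 = x$c1, c2 = x$c2, kappa = x$config$kappa,
    n_components = length(x$components),
    rho_train_1 = if (nrow(x$results) > 0) x$results$rho_train[1] else
      NA_real_,
    min_p_value = if ("p_value" %in% names(x$results)) {
      min(x$results$p_value)
    } else {
      NA_real_
    })
}

#' Plot the sparse sub-kernel weights of a fitted model
#'
#' Bar chart of the non-zero weights, faceted by component, with the two
#' views side by side — a quick read of which features (or feature pairs)
#' each canonical component selected.
#'
#' @param object A `tskcca` object.
#' @param components Components to show (default: all).
#' @param zero_tol Weights at or below this are hidden.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tskcca
#' @export
autoplot.tskcca <- function(object, components = NULL, zero_tol = 1e-8, ...) {
  df <- tidy.tskcca(object, zero_tol = zero_tol)
  if (!is.null(components)) {
    df <- dplyr::filter(df, .data$component %in% components)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kernel, y = .data$weight,
                                   fill = .data$view)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(component ~ view, scales = "free_x",
                        labeller = ggplot2::labeller(
                          component = function(i) paste("component", i))) +
    ggplot2::labs(x = NULL, y = "sub-kernel weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an HSIC dependence matrix
#'
#' Heat map of the pairwise HSIC values between the two banks' sub-kernels.
#'
#' @param M A matrix from [hsic_matrix()] (or a `tskcca` fit, whose `M` is
#'   used).
#' @return A ggplot object.
#' @export
plot_hsic_matrix <- function(M) {
  if (inherits(M, "tskcca")) M <- M$M
  df <- tibble::as_tibble(as.data.frame(as.table(M), stringsAsFactors = FALSE))
  names(df) <- c("x_kernel", "z_kernel", "hsic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_kernel, y = .data$x_kernel,
                                   fill = .data$hsic)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "z sub-kernels", y = "x sub-kernels", fill = "HSIC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
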