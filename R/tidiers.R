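#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("Beta-uniform mixture fit (n = %d): pi = %.3f, a = %.3f\n",
              x$n, x$pi, x$a))
  if (!is.na(x$tau)) {
    cat(sprintf("  tau = %.3g at FDR %.3g\n", x$tau, x$fdr))
  }
  if (x$no_signal) cat("  note: fit indistinguishable from pure noise\n")
  invisible(x)
}

#' @export
tidy.bum_fit <- function(x, ...) {
  tibble::tibble(term = c("pi", "a"), estimate = c(x$pi, x$a))
}

#' @export
glance.bum_fit <- function(x, ...) {
  tibble::tibble(pi = x$pi, a = x$a, pi_upper = x$pi_upper,
                 tau = x$tau, fdr = x$fdr,
                 log_likelihood = x$log_likelihood, n = x$n,
                 no_signal = x$no_signal)
}

#' Diagnostic plot of a beta-uniform mixture fit
#'
#' Histogram of the fitted p-values (density scale) with the fitted
#' mixture density and its uniform floor overlaid, and the FDR threshold
#' tau when set.
#'
#' @param object A `bum_fit`.
#' @param p_values The p-values the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bum_fit <- function(object, p_values, ...) {
  grid <- tibble::tibble(x = seq(0.001, 1, length.out = 400)) |>
    dplyr::mutate(f = bum_density(.data$x, object))
  gg <- ggplot2::ggplot(tibble::tibble(p = p_values), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey85", colour = "grey40") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$f),
                       colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = object$pi, linetype = "dashed") +
    ggplot2::labs(x = "p-value", y = "density",
                  title = sprintf("BUM fit: pi = %.2f, a = %.2f",
                                  object$pi, object$a))
  if (!is.na(object$tau)) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$tau,
                                   colour = "#2166ac", linetype = "dotted")
  }
  gg
}

#' Node frequency plot for an Active Module Group
#'
#' @param object An `amg`.
#' @param ... Unused.
#' @return A ggplot object: per-node selection frequencies with the AMG
#'   threshold marked.
#' @export
autoplot.amg <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(node = factor(.data$node, levels = rev(.data$node)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$node,
                                   colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "relative frequency over solutions", y = NULL,
                  colour = "in AMG")
}

#' Variance and loading plot for a change PCA
#'
#' @param object A `pca_changes`.
#' @param components Components shown in the loading panel.
#' @param ... Unused.
#' @return A ggplot object of loadings on the first two components.
#' @export
autoplot.pca_changes <- function(object, components = 1:2, ...) {
  rot <- object$fit$rotation[, components, drop = FALSE]
  df <- tibble::as_tibble(rot, rownames = "metabolite")
  nm <- colnames(rot)
  vf <- object$variance_fraction[components]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$metabolite), size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", nm[1], 100 * vf[1]),
      y = sprintf("%s (%.0f%%)", nm[2], 100 * vf[2]),
      title = "Metabolite loadings on top principal components")
}
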