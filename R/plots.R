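#' @export
autoplot.lfq_pca <- function(object, annotation = NULL, components = c(1, 2),
                             ...) {
  df <- tidy(object)
  pcs <- paste0("PC", components)
  if (!is.null(annotation)) {
    df$cohort <- annotation$cohort[match(df$sample, annotation$sample)]
  }
  ev <- object$explained_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[pcs[1]]], y = .data[[pcs[2]]],
    colour = if (is.null(annotation)) NULL else .data$cohort)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * ev[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * ev[components[2]]),
      colour = "cohort"
    ) +
    ggplot2::theme_minimal()
  p
}

#' @export
autoplot.correlation_report <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(sample_a = rownames(m), sample_b = colnames(m))
  df$pcc <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(min(m), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano plot with the S0 significance boundary
#'
#' @param result tibble from [s0_significance()].
#' @param label optional character vector of labels, same length.
#' @return A ggplot object: log2 fold change against -log10 p, significant
#'   proteins highlighted.
#' @export
plot_volcano <- function(result, label = NULL) {
  df <- result
  df$neglog10p <- -log10(pmax(df$p, .Machine$double.xmin))
  if (!is.null(label)) df$label <- label
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logfc, y = .data$neglog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.two_group_fit <- function(object, ...) {
  grid <- object$grid
  long <- tidyr::pivot_longer(
    tibble(z = grid$z, marginal = grid$f_hat,
           scaled_null = object$pi0 * grid$f0),
    -"z", names_to = "component", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z", y = "density",
                  title = sprintf("two-group model (pi0 = %.2f)", object$pi0)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.marker_call <- function(object, ...) {
  tau <- attr(object, "tau") %||% 0.9
  ggplot2::ggplot(object, ggplot2::aes(x = .data$posterior_1,
                                       y = .data$posterior_2,
                                       colour = .data$pattern)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = tau, linetype = 2) +
    ggplot2::geom_vline(xintercept = tau, linetype = 2) +
    ggplot2::labs(x = "posterior (END → EMT)",
                  y = "posterior (EMT → cancer)", colour = "pattern") +
    ggplot2::theme_minimal()
}
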