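# ggplot2 displays: trace plots, the saturation curve, and the Bayes-factor
# comparison table.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace plot of sampled log-likelihood and tree length
#'
#' @param object An `mcmc_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcmc_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(object$samples[c("generation", "lnL", "TL")],
                            c("lnL", "TL"))
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$config$burn_in_generations,
                        linetype = 2) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "generation", y = NULL,
                  title = paste("MCMC trace:", object$run_label))
}

#' Likelihood-saturation curve over mixture components
#'
#' @param object Result of [saturation_analysis()] / [saturation_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean lnL against K with the plateau marked.
#' @export
autoplot.tbl_saturation <- function(object, ...) plot_saturation(object)

#' @rdname autoplot.tbl_saturation
#' @param sat Saturation tibble.
#' @export
plot_saturation <- function(sat, ...) {
  pk <- attr(sat, "plateau_k")
  ggplot2::ggplot(sat, ggplot2::aes(.data$k, .data$lnl)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = pk, linetype = 2, colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = sat$k) +
    ggplot2::labs(x = "number of GTR+Gamma matrices (K)",
                  y = "mean post-burn-in lnL",
                  title = "Likelihood saturation over mixture components")
}

#' Heatmap of pairwise log Bayes factors
#'
#' @param object A `regime_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regime_comparison <- function(object, ...) {
  bf <- object$bf_matrix
  df <- tibble::as_tibble(as.data.frame.table(bf, responseName = "logBF"))
  names(df)[1:2] <- c("regime_a", "regime_b")
  ggplot2::ggplot(df, ggplot2::aes(.data$regime_b, .data$regime_a,
                                   fill = .data$logBF)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$logBF)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise log Bayes factors")
}
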