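# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of a TWAS scan
#'
#' One point per tissue-specific gene model at its TSS, with the
#' Bonferroni threshold drawn as a horizontal line.
#'
#' @param object A `twas_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twas_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tss, y = -log10(.data$p_twas),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "transcription start site (bp)",
                  y = expression(-log[10](p[TWAS])),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Per-block local genetic correlation plot
#'
#' Local genetic covariance against block midpoint, highlighting blocks
#' passing the per-block Bonferroni threshold.
#'
#' @param object A `local_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.local_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$rho,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "block midpoint (bp)",
                  y = "local genetic covariance",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Partition-level correlation plot of a causality contrast
#'
#' Set-level correlation with 1.96-SE error bars per block partition, the
#' flat-file analogue of a trait-specific-region causality figure.
#'
#' @param object A `causality_contrast` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.causality_contrast <- function(object, ...) {
  d <- object$partitions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "set-level genetic correlation",
                  subtitle = paste("verdict:", object$verdict)) +
    ggplot2::theme_minimal()
}
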