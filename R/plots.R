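#' Plot the outlier-bin fold-change distribution of a scaling fit
#'
#' Histogram of the per-bin log2 fold changes with the median (the
#' reciprocal of the scaling factor) marked.
#'
#' @param object A `scaling_fit` from [estimate_scaling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fc))) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = log2(object$median_fc),
                        colour = "red", linetype = 2) +
    ggplot2::labs(
      x = "log2 fold change (treated / untreated) at outlier bins",
      y = "bins",
      title = sprintf("Outlier-bin fold changes (k = %d): factor = %.3f",
                      object$k, object$factor)
    )
}

#' Plot a threshold-sensitivity sweep
#'
#' Estimated scaling factor as a function of the number of outlier bins
#' considered; a flat curve means the estimate does not hinge on the
#' threshold.
#'
#' @param object A `k_sweep` from [sweep_outlier_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "outlier bins considered (k)", y = "scaling factor",
                  title = "Sensitivity of the scaling factor to the outlier threshold")
}

#' Plot ranked promoter fold changes
#'
#' The sorted fold-change curve over promoters (log2 scale); under a global
#' loss of the mark nearly the entire curve lies below 0.
#'
#' @param object A `promoter_fc` from [promoter_fold_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promoter_fc <- function(object, ...) {
  d <- object[object$defined, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$log2_fc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "promoters ranked by fold change",
                  y = "log2 fold change (treated rescaled / untreated)",
                  title = "Sorted promoter fold change")
}

#' Plot PTM log2 ratios between conditions
#'
#' Bar chart of the log2 (treated/untreated) ratio per modification state,
#' grouped by residue site; states significant at p < 0.05 are filled.
#'
#' @param object A `ptm_comparison` from [compare_ptm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ptm_comparison <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- paste0(d$site, d$state)
  d$significant <- !is.na(d$p_value) & d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$log2_ratio),
                                  y = .data$log2_ratio, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "grey70"),
                               name = "p < 0.05") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 ratio (treated / untreated)",
                  title = "Histone-PTM relative-abundance changes")
}
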