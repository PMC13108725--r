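#' Ranked mean-score plot for one analyte
#'
#' Units ordered by decreasing donor-averaged modified z-score, with SEM
#' error bars and a dashed line at the control units' mean score.
#'
#' @param object a `polar_scores` object.
#' @param analyte analyte to display (default: first retained).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot polar_scores
#' @export
autoplot.polar_scores <- function(object, analyte = NULL, ...) {
  analyte <- analyte %||% object$retained_analytes[1]
  d <- dplyr::filter(object$per_unit, .data$analyte == !!analyte)
  ctrl <- dplyr::filter(d, .data$is_control)
  d <- dplyr::filter(d, !.data$is_control)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$unit, -.data$mean_z), y = .data$mean_z)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_z - .data$sem,
                                        ymax = .data$mean_z + .data$sem),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean modified z-score",
                  title = analyte) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (nrow(ctrl) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = mean(ctrl$mean_z),
                                 linetype = "dashed")
  }
  p
}

#' Volcano plot of a quartile DE result
#'
#' Shrunken log2 fold change against -log10 adjusted p, significant genes
#' highlighted.
#'
#' @param de tibble from [quartile_de()] or [call_de()].
#' @return a ggplot.
#' @export
plot_volcano <- function(de) {
  check_columns(de, c("lfc_shrunken", "p_adj", "significant"), "DE result")
  ggplot2::ggplot(de, ggplot2::aes(x = .data$lfc_shrunken,
                                   y = -log10(.data$p_adj),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "shrunken log2 fold change",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Normalized enrichment score per gene set, dot size showing the
#' leading-edge gene ratio and colour the BH-adjusted permutation p.
#'
#' @param enr tibble from [preranked_gsea()].
#' @param top number of sets (by |NES|) to display.
#' @return a ggplot.
#' @export
plot_enrichment_dots <- function(enr, top = 20) {
  d <- dplyr::slice_max(enr, abs(.data$nes), n = top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$nes, y = stats::reorder(.data$set_name, .data$nes),
    size = .data$gene_ratio, colour = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "grey70") +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Residual diagnostics for a mixed-model fit
#'
#' Residual-vs-fitted and normal Q-Q panels of the marginal residuals, the
#' usual by-inspection checks of homoscedasticity and normality.
#'
#' @param object an `ri_fit`.
#' @param ... unused.
#' @return a ggplot (two facets).
#' @method autoplot ri_fit
#' @export
autoplot.ri_fit <- function(object, ...) {
  r <- object$y - object$fitted_fixed
  d <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted",
                   x = object$fitted_fixed, y = r),
    tibble::tibble(panel = "normal Q-Q",
                   x = qnorm(stats::ppoints(length(r)))[order(order(r))],
                   y = r)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "residual") +
    ggplot2::theme_minimal()
}
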