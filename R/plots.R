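#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for eoatlas results
#'
#' `autoplot()` methods produce the conventional display for each result
#' type: a compositional PCA biplot, an interaction-strength heat map, a
#' lasso predicted-vs-observed scatter, and an NMF error trace. Abundance
#' and differential-expression tibbles have dedicated `plot_*()` helpers.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a [ggplot2::ggplot].
#' @name eoatlas-plots
NULL

#' @rdname eoatlas-plots
#' @param colour_by sample-table column (joined by `sample_id`) used to
#'   colour the score plot, e.g. condition.
#' @param samples optional sample table supplying `colour_by`.
#' @export
autoplot.eoe_pca <- function(object, colour_by = NULL, samples = NULL, ...) {
  df <- object$scores
  if (!is.null(samples) && !is.null(colour_by)) {
    df <- dplyr::left_join(df, samples, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(colour_by) && colour_by %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @rdname eoatlas-plots
#' @export
autoplot.eoe_interaction <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$strength), .name_repair = "minimal")
  names(df) <- c("source", "target", "strength")
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "receptor side", y = "ligand side",
                  fill = paste0("top-", object$k, "\nstrength")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname eoatlas-plots
#' @export
autoplot.eoe_lasso <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$loocv_predicted, .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "LOOCV prediction", y = "observed fraction",
                  subtitle = sprintf("slope p = %.3g, r = %.2f",
                                     object$slope_p, object$r)) +
    ggplot2::theme_minimal()
}

#' @rdname eoatlas-plots
#' @export
autoplot.eoe_nmf <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$error_trace),
                       error = object$error_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "Frobenius reconstruction error") +
    ggplot2::theme_minimal()
}

#' Volcano-style display of a differential-abundance table
#'
#' @param abundance tibble from [nb_abundance()] or
#'   [quantile_rank_regression()].
#' @param contrast contrast to display (default the first).
#' @return a [ggplot2::ggplot].
#' @export
plot_abundance <- function(abundance, contrast = NULL) {
  if (is.null(contrast)) contrast <- abundance$contrast[1]
  df <- dplyr::filter(abundance, .data$contrast == !!contrast)
  df$stars <- dplyr::case_when(df$fdr < 0.001 ~ "***", df$fdr < 0.01 ~ "**",
                               df$fdr < 0.05 ~ "*", TRUE ~ "")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$cell_type, .data$estimate))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$fdr < 0.05)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2) +
    ggplot2::labs(x = "log fold change (condition effect)", y = NULL,
                  fill = "FDR < 0.05", title = contrast) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de tibble from [de_logistic()] (optionally after
#'   [ambient_filter()]).
#' @return a [ggplot2::ggplot]; significant genes (adjusted p < 0.001,
#'   fold change > 1.5) in red, ambient-filtered genes hollow.
#' @export
plot_de_volcano <- function(de) {
  de$class <- ifelse(de$significant, "significant", "ns")
  shape <- if ("ambient_filtered" %in% names(de))
    ifelse(de$ambient_filtered, 1, 19) else 19
  ggplot2::ggplot(de, ggplot2::aes(.data$log2_fc,
                                   -log10(pmax(.data$p_bonferroni, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), shape = shape) +
    ggplot2::scale_colour_manual(values = c(significant = "red", ns = "grey50")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
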