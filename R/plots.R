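# ggplot2 views of the result tables.

#' Scatter plot of polar fluorescence percentages
#'
#' Percentage of total fluorescence at pole 2 against pole 1 for all cells
#' with at least one polar cluster, with the symmetry line. Points colour by
#' replicate when a `replicate` column is present, otherwise by category.
#'
#' @param object A `rodpol_quant` tibble from [quantify_cells()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rodpol_quant <- function(object, ...) {
  rep_col <- if ("replicate" %in% names(object)) object$replicate else NULL
  df <- scatter_table(object, replicate = rep_col)
  colour_var <- if (is.null(rep_col)) "category" else "replicate"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pole1_pct, y = .data$pole2_pct,
                                   colour = .data[[colour_var]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "% total fluorescence at pole 1",
                  y = "% total fluorescence at pole 2") +
    ggplot2::theme_classic()
}

#' Bar diagram of localization categories
#'
#' Percentage of cells per localization category, one bar group per
#' replicate (pooled row included).
#'
#' @param object A `rodpol_popsummary` tibble from [aggregate_population()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rodpol_popsummary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::starts_with("pct_"),
    names_to = "category", names_prefix = "pct_", values_to = "pct")
  long$category <- factor(long$category, levels = LOCALIZATION_LEVELS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$replicate, y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack", width = 0.7) +
    ggplot2::labs(x = NULL, y = "% of cells") +
    ggplot2::theme_classic()
}

#' Speed and reversal distributions of tracked cells
#'
#' @param object A `rodpol_motility` tibble from [summarize_motility()].
#' @param ... Unused.
#' @return A ggplot object (per-cell mean speed, jittered, with the cohort
#'   mean marked).
#' @export
autoplot.rodpol_motility <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "cells", y = .data$mean_speed_um_min)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "black") +
    ggplot2::labs(x = NULL, y = "Mean speed (µm/min)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
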