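# Population-level aggregation of per-cell quantifications, the scatter-plot
# table (pole 2 % vs pole 1 %), and the equal-variance two-sample t-test used
# for strain comparisons.

#' Aggregate per-cell quantifications into population summaries
#'
#' Produces one row per replicate plus a pooled row. Category percentages are
#' fractions of quantified cells; `mean_polar_pct` and `mean_cytoplasmic_pct`
#' average the per-cell polar (pole 1 + pole 2) and cytoplasmic percentages
#' over all cells, including cluster-free (diffuse) cells, which contribute
#' 0% polar signal. The pooled row averages the replicate means with equal
#' weight per replicate — matching how multi-experiment means are usually
#' reported — unless `pooling = "cell"` is chosen, which pools all cells
#' directly.
#'
#' @param cells A `rodpol_quant` tibble from [quantify_cells()].
#' @param replicate Replicate labels, one per cell (defaults to a single
#'   replicate), or the name of a column in `cells`.
#' @param pooling `"replicate"` (mean of replicate means, default) or
#'   `"cell"` (cell-weighted).
#' @return A tibble of class `rodpol_popsummary`: `replicate`, `n_cells`,
#'   `pct_unipolar`, `pct_bipolar_asymmetric`, `pct_bipolar_symmetric`,
#'   `pct_diffuse`, `mean_polar_pct`, `mean_cytoplasmic_pct`. The last row is
#'   the pooled summary (`replicate == "pooled"`).
#' @export
aggregate_population <- function(cells, replicate = NULL,
                                 pooling = c("replicate", "cell")) {
  pooling <- match.arg(pooling)
  if (nrow(cells) == 0L) abort("No quantified cells to aggregate.")
  if (is.null(replicate)) {
    replicate <- rep("1", nrow(cells))
  } else if (is.character(replicate) && length(replicate) == 1L &&
             replicate %in% names(cells)) {
    replicate <- as.character(cells[[replicate]])
  } else if (length(replicate) != nrow(cells)) {
    abort("`replicate` must name a column or give one label per cell.")
  }
  replicate <- as.character(replicate)

  summarize_group <- function(df) {
    cat_counts <- table(factor(df$category, levels = LOCALIZATION_LEVELS))
    tibble(
      n_cells = nrow(df),
      pct_unipolar = 100 * cat_counts[["unipolar"]] / nrow(df),
      pct_bipolar_asymmetric =
        100 * cat_counts[["bipolar_asymmetric"]] / nrow(df),
      pct_bipolar_symmetric =
        100 * cat_counts[["bipolar_symmetric"]] / nrow(df),
      pct_diffuse = 100 * cat_counts[["diffuse"]] / nrow(df),
      mean_polar_pct = mean(df$pole1_pct + df$pole2_pct),
      mean_cytoplasmic_pct = mean(df$cytoplasmic_pct)
    )
  }

  reps <- split(as_tibble(cells), replicate)
  empty <- vapply(reps, function(df) nrow(df) == 0L, logical(1))
  if (any(empty)) {
    warn(sprintf("Empty replicate(s) excluded: %s.",
                 paste(names(reps)[empty], collapse = ", ")))
    reps <- reps[!empty]
  }
  per_rep <- dplyr::bind_rows(lapply(reps, summarize_group), .id = "replicate")
  pooled <- if (pooling == "replicate") {
    dplyr::bind_cols(
      tibble(replicate = "pooled", n_cells = sum(per_rep$n_cells)),
      dplyr::summarise(per_rep, dplyr::across(
        c("pct_unipolar", "pct_bipolar_asymmetric", "pct_bipolar_symmetric",
          "pct_diffuse", "mean_polar_pct", "mean_cytoplasmic_pct"), mean))
    )
  } else {
    dplyr::mutate(summarize_group(dplyr::bind_rows(reps)),
                  replicate = "pooled", .before = 1L)
  }
  out <- dplyr::bind_rows(per_rep, pooled)
  class(out) <- c("rodpol_popsummary", class(out))
  out
}

#' Scatter-plot table of polar fluorescence percentages
#'
#' One row per cell carrying at least one polar cluster, for plotting the
#' percentage of total fluorescence at pole 2 against that at pole 1. Since
#' pole 1 is by definition the brighter pole, all points lie on or below the
#' symmetry line `pole2_pct == pole1_pct`.
#'
#' @param cells A `rodpol_quant` tibble from [quantify_cells()].
#' @param replicate Optional replicate labels as in [aggregate_population()].
#' @return Tibble with `pole1_pct`, `pole2_pct`, `replicate`, `category`.
#' @export
scatter_table <- function(cells, replicate = NULL) {
  if (is.null(replicate)) {
    replicate <- rep("1", nrow(cells))
  } else if (is.character(replicate) && length(replicate) == 1L &&
             replicate %in% names(cells)) {
    replicate <- as.character(cells[[replicate]])
  }
  out <- as_tibble(cells)
  out$replicate <- as.character(replicate)
  out <- out[out$category != "diffuse", , drop = FALSE]
  dplyr::select(out, "pole1_pct", "pole2_pct", "replicate", "category")
}

#' Two-tailed Student's t-test for samples with equal variances
#'
#' The pooled-variance two-sample t-test with `n_a + n_b - 2` degrees of
#' freedom and a two-sided p-value — the standard test for comparing strain
#' means of motility or localization metrics. Degenerate inputs with zero
#' pooled variance return `t = 0, p = 1` when the means are equal and raise
#' an error otherwise.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return An object of class `rodpol_ttest`; see [tidy.rodpol_ttest()].
#' @export
t_test_equal_var <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each sample needs at least 2 observations.")
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, p.value = 1,
                  df = length(a) + length(b) - 2L)
    } else {
      abort("Zero pooled variance with unequal means: t is undefined.")
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
                df = unname(ht$parameter))
  }
  structure(list(statistic = res$statistic, p.value = res$p.value,
                 df = res$df, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "rodpol_ttest")
}

#' @export
print.rodpol_ttest <- function(x, ...) {
  cat(sprintf(
    "Two-tailed Student's t-test (equal variances)\n  t = %.4g, df = %d, p = %.4g\n  mean a = %.4g (n = %d), mean b = %.4g (n = %d)\n",
    x$statistic, x$df, x$p.value, x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Tidy an equal-variance t-test
#'
#' @param x A `rodpol_ttest` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (mean difference a - b), `statistic`,
#'   `p.value`, `parameter` (degrees of freedom), `method`.
#' @export
tidy.rodpol_ttest <- function(x, ...) {
  tibble(estimate = x$mean_a - x$mean_b, statistic = x$statistic,
         p.value = x$p.value, parameter = x$df,
         method = "Two-sample t-test, pooled variance, two-tailed")
}

#' @rdname tidy.rodpol_ttest
#' @export
glance.rodpol_ttest <- function(x, ...) {
  tidy(x)
}
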