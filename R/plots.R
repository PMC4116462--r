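# ggplot2 views of the pipeline's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram
#'   geom_point geom_jitter geom_abline labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot per-step feature removals of a QC report
#'
#' @param object A `qc_report` from [run_qc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%d %s", df$step, df$action)
  ggplot(df, aes(x = stats::reorder(.data$label, .data$step), y = .data$removed)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "features removed", title = "Quality-control cascade") +
    theme_minimal()
}

#' Plot significant-feature counts per factor
#'
#' @param object A `factor_results` tibble from [fit_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot factor_results
#' @export
autoplot.factor_results <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$column, .data$factor)
  ggplot(df, aes(x = .data$factor, y = .data$n, fill = .data$column)) +
    geom_col(position = "dodge") +
    labs(
      x = NULL, y = "significant features",
      title = "Features associated with each model factor"
    ) +
    theme_minimal()
}

#' Plot the distribution of intraclass correlations
#'
#' @param object A `heritability_result` from [heritability_screen()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heritability_result
#' @export
autoplot.heritability_result <- function(object, bins = 40, ...) {
  ggplot(object, aes(x = .data$t)) +
    geom_histogram(bins = bins, fill = "grey35") +
    facet_wrap(~column) +
    labs(
      x = "intraclass correlation t", y = "features",
      title = "Heritability screen"
    ) +
    theme_minimal()
}

#' Plot latent scores of a (sparse) PLS-DA model
#'
#' First two latent components (or the single component against its
#' class) with training-class labels.
#'
#' @param object An `spls_da` model from [spls_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spls_da
#' @export
autoplot.spls_da <- function(object, ...) {
  sc <- object$scores
  df <- tibble::tibble(
    comp1 = sc[, 1],
    comp2 = if (ncol(sc) >= 2) sc[, 2] else NA_real_,
    class = object$labels
  )
  if (ncol(sc) >= 2) {
    ggplot(df, aes(x = .data$comp1, y = .data$comp2, colour = .data$class)) +
      geom_point() +
      labs(x = "component 1", y = "component 2", title = "Latent scores") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$class, y = .data$comp1, colour = .data$class)) +
      geom_jitter(width = 0.15, height = 0) +
      labs(x = NULL, y = "component 1", title = "Latent scores") +
      theme_minimal()
  }
}

#' Plot predicted against observed age
#'
#' @param object A `validation_summary` from [train_test_r2()] (must
#'   carry per-repeat predictions).
#' @param which_rep Repeat to display (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_age_prediction <- function(object, which_rep = 1, ...) {
  stopifnot(inherits(object, "validation_summary"))
  if (is.null(object$predictions)) abort("no per-repeat predictions stored")
  df <- dplyr::filter(object$predictions, .data$rep == which_rep)
  ggplot(df, aes(x = .data$observed, y = .data$predicted)) +
    geom_point() +
    geom_abline(linetype = "dashed", colour = "grey50") +
    labs(
      x = "observed age (d)", y = "predicted age (d)",
      title = sprintf("Held-out age prediction (repeat %d)", which_rep)
    ) +
    theme_minimal()
}

#' Plot pathway enrichment results
#'
#' @param object An `enrichment_result` from [enrich()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- dplyr::mutate(object, neglog = -log10(.data$p_emp))
  ggplot(df, aes(
    x = .data$neglog,
    y = stats::reorder(.data$pathway_id, .data$neglog),
    size = .data$observed
  )) +
    geom_point() +
    labs(
      x = expression(-log[10] ~ "empirical p"), y = NULL,
      size = "selected hits", title = "Pathway enrichment"
    ) +
    theme_minimal()
}
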